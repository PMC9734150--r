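---
title: "Allosteric communication networks and activation kinetics with allonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allosteric communication networks and activation kinetics with allonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

## The scientific problem

ATP phosphoribosyltransferase (ATPPRT) catalyses the first step of
histidine biosynthesis. In the hetero-octameric form studied here, a
regulatory subunit (HisZ) binds the catalytic dimer (HisGS) roughly 20 Å
away from the active site and activates catalysis allosterically: binding
constrains the conformational dynamics of the dimer so that an arginine
side chain reaching across the dimer interface is held in a catalytically
productive rotamer next to the pyrophosphate moiety of the substrate
PRPP. `allonet` packages the two quantitative workflows this picture
rests on:

1. a **dynamics workflow** — from a conformational ensemble to dynamic
   cross-correlation matrices (DCCM), correlation-weighted residue
   graphs, shortest path maps (SPM), characteristic path length (CPL)
   with node-weakening rankings, dynamical flexibility indices (DFI) and
   side-chain–ligand distance distributions; and
2. a **kinetics workflow** — evaluators and nonlinear fits for the four
   measurement models (Michaelis–Menten saturation, thermal-melt sigmoid,
   tight-binding activation titration, Hill sigmoid), the complex-
   concentration calculation, and the activation/impairment fold
   arithmetic.

Because running molecular dynamics is out of scope, the package carries a
first-class synthetic-ensemble generator: Gaussian fluctuations from an
elastic-network covariance, with a "regulator-bound" variant. Everything
downstream of trajectory generation is exactly the analysis that would be
applied to real ensembles.

## The synthetic ensemble generator

`build_toy_network()` places harmonic springs between all point pairs
within a distance cutoff. Two fluctuation models are derived from it by
`network_covariance()`:

* **scalar mode** (default for tests): the covariance is the Moore–
  Penrose pseudo-inverse of the Kirchhoff (connectivity) matrix, the
  Gaussian-network convention with one coordinate per residue. Sampling
  drives the three Cartesian axes independently with this covariance, so
  the analytic displacement correlation of the ensemble is available in
  closed form — the property every estimator test leans on.
* **three_d mode**: the pseudo-inverse of the 3N anisotropic-network
  Hessian.

Zero modes (1 for the connectivity matrix, 6 rigid-body modes for the
Hessian) are removed before pseudo-inversion, with eigenvalues below
`1e-8` times the largest treated as zero; finding a different number than
expected is an error rather than a silent repair, because it signals a
disconnected or degenerate geometry. One geometric subtlety matters for
3-D tests: a pairwise-spring Hessian has rank at most the number of
springs, so a straight chain is *always* floppier than the six rigid-body
modes. Helical chain fixtures with springs spanning about three sequence
neighbours are used wherever a full-rank 3-D model is needed.

`make_toy_dimer()` is the study system: two 4×3 residue grids (3.8 Å
spacing, the Cα virtual-bond length) facing each other across a 4.5 Å
gap, chain-qualified labels (`A:1` … `B:12`), and *soft* inter-subunit
springs (stiffness 0.2 versus 1 intra-subunit) — a loose, nonactivated
interface. `stiffen_intersubunit(net, 5)` is the regulator-bound state:
the inter-subunit couplings are brought up to the intra-subunit
stiffness, emulating the regulator clamping the interface. This pairing
was chosen, once, because it reproduces the qualitative physics the
pipeline is meant to detect — inter-subunit correlations rise on
binding, inter-subunit edges are recruited into the SPM, and the largest
DFI changes localize at the interface nodes. The default ensemble size
is 5,000 frames; at that depth the empirical DCCM sits within ±0.05 of
the analytic correlation, which is the resolution the network stage
needs. Sampling is seed-deterministic throughout, and the distance-series
generator re-draws (rather than truncates) negative values so the mixture
shape near each mode is preserved.

What the generator deliberately does **not** emulate: anharmonicity,
solvent friction, mass effects, side-chain rotamer jumps (the bimodal
distance series is generated directly as a Gaussian mixture, not from the
elastic network), and the 416-residue scale of the real dimer. Passing
tests therefore certify the *estimators and graph algorithms*, not the
force field realism of any particular protein.

## Ensemble statistics

`superpose_ensemble()` performs least-squares rigid-body alignment
(Kabsch, with the determinant correction so reflections are never
returned) against a fixed frame, an external structure, or the ensemble
mean; the mean reference is iterated to convergence (mean shift below
`1e-6` Å, at most 20 iterations). The DCCM is

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
{\sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}},$$

with displacements taken from the ensemble-mean positions. Superposition
before the DCCM is the default, because rigid-body motion contaminates
correlations; ensembles drawn directly from a covariance model are
already expressed in the model frame and may skip it
(`superpose = FALSE`). Matrices are compared with Spearman's rank
correlation over the strict upper triangle (diagonal excluded — it is
identically 1 and carries no information), with the two-sided rank-order
test. Mass-weighting is not applied; displacements are per-point and
unweighted.

`distance_distribution()` smooths a distance series with a Gaussian KDE
(Silverman's rule by default, overridable) on `[0, max + 3·bw]` and
reports modes as local maxima above 10 % of the global density maximum.
Two mixture components closer than the bandwidth merge into one detected
mode — documented behaviour, not an error. Mode recovery to within
0.1 Å is expected for component separations of at least 4σ at 5,000+
draws.

## The residue graph and shortest path map

`build_residue_graph()` connects residues i and j when they are within
the contact cutoff in at least a minimum fraction of frames *and*
|C_ij| clears a floor. Defaults — 6 Å contact cutoff, 0.5 occupancy,
0.05 correlation floor — are conventional residue-network choices and are
all exposed and echoed into run manifests, since no single standard
exists. The edge length is $-\log |C_{ij}|$: monotone decreasing in
correlation strength and additive along paths, so "short" means
"strongly correlated". A perfect correlation would give length 0 and is
clamped to `1e-6` (reported when it happens); signed correlations are
kept on the edges, the absolute value enters only the length.

Shortest paths use Dijkstra's algorithm with a deterministic tie-break:
among equal-length paths the lexicographically smallest node sequence
wins, making SPM usage counts reproducible to the bit. `compute_spm()`
accumulates one count per edge on the shortest path of *every ordered
node pair*, normalizes all usages by the maximum, and keeps edges with
normalized usage ≥ 0.3 as the SPM. The alternative reading — tracing
only the first-to-last residue pair — is available as
`pairs = "endpoints"`; the all-pairs form is the default because a
single-pair map degenerates to one path and cannot express the
"communication highways" interpretation. The normalization constant and
display threshold are configurable because no canonical values exist.

CPL is the mean shortest-path length over unordered *reachable* pairs,
with the reachable fraction reported. On disconnected graphs this keeps
CPL finite and node-weakening rankings well-defined; removals that
disconnect the remainder are flagged per node. `node_weakening()` removes
each candidate node with its incident edges, recomputes CPL, and ranks by
|ΔCPL| — the screen used to nominate interface mutations.

## Dynamical flexibility index

Under linear response, the displacement of residue i caused by a force
**f** at residue j is the covariance block $G_{ij}$ acting on **f**.
Averaging the squared response isotropically over force directions has
the closed form $R_{ij} = \sqrt{\mathrm{tr}(G_{ij}^\top G_{ij})/3}$ in
3-D; in scalar mode it collapses to $|{\rm cov}_{ij}|$. The DFI of
residue i is its row share $\sum_j R_{ij} / \sum_{kj} R_{kj}$, which sums
to 1 and is invariant to any uniform scaling of the covariance
(temperature factors drop out). Direction-averaging is analytic; a
Monte-Carlo averager (`perturbation_response_mc()`) is retained purely as
a cross-check oracle. DFI is computed from the same covariance used
elsewhere in the pipeline (model-derived here; trajectory-estimated
covariances plug in identically), and the source is recorded on the
profile.

## Kinetics

The four measurement models, in the package's notation ($S$ substrate
mM; $T$ °C; $Z$ regulator µM; $G$ catalytic-subunit µM, fixed):

* saturation: $v/E_T = k_{cat} S / (K_M + S)$;
* thermal melt: $F_U = LL + (UL - LL)/(1 + e^{(T_m - T)/c})$;
* tight-binding activation:
  $v = V_{max}\,\bigl(G + Z + K_D^{app} - \sqrt{(G + Z + K_D^{app})^2 - 4 G Z}\bigr)/(2G)$;
* cooperative activation (standard Hill form):
  $v = V_{max} Z^h / (K_{0.5}^h + Z^h)$.

The tight-binding quadratic is the depletion-aware curve: when $Z$ is
comparable to both $G$ and $K_D$, free regulator cannot be equated with
total regulator, and the quadratic lies strictly below the same-$K$
hyperbola. The companion complex-concentration expression (the same
quadratic without the $1/G$ normalization) gives the assembled holoenzyme
concentration, bounded by $\min(G, Z)$ and symmetric in $G$ and $Z$; it
is the conversion used when turnover numbers must be expressed per
holoenzyme rather than per total subunit at the assay's regulator
concentration. Discriminants that dip below zero by rounding are clamped;
genuinely negative ones are an error.

The Hill equation is printed in some sources with $K_{0.5}$ *not* raised
to $h$, which gives the constant units of concentration$^h$. The
dimensionally consistent standard form is the default; the as-printed
variant is preserved verbatim behind `form = "as_printed"` for
comparisons with fits made in that parameterization. When a sigmoidal
titration cannot be run under pseudo-first-order conditions (catalyst and
regulator at comparable concentrations), the Hill fit is descriptive
only — it quantifies sigmoidicity, not an equilibrium constant — and is
documented as such.

Fitting is unweighted nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`, objective tolerance `1e-10`), with data-driven starting
values: plateau rate for $k_{cat}$/$V_{max}$, half-saturating
concentration for $K_M$/$K_D$/$K_{0.5}$, mid-signal temperature for
$T_m$. Uncertainties are asymptotic standard errors from the Jacobian,
matching the mean ± fitting-error convention of bench nonlinear
regression software. The Hill coefficient is bounded to (0, 10] during
fitting; negative parameter estimates are rejected rather than reported.

`fold_change()` reports the exact ratio of two rate constants plus an
integer fold rounded half-away-from-zero. Published fold tables are
typically computed from unrounded measurements, so folds recomputed from
*printed* rate constants can differ from printed folds by one unit in the
last digit; the exact ratio is always carried alongside the integer for
this reason.

## Orchestration and reproducibility

`run_dynamics_pipeline()` and `run_kinetics_pipeline()` execute the two
workflows from a validated `pipeline_config()` (unknown keys are
rejected); every stage writes plain-text outputs (CSV/TSV matrices and
tables, GraphML graphs, JSON fit reports) and a JSON manifest recording
the package version, the root seed, every parameter actually used, and
MD5 hashes of all outputs. All randomness flows from the one root seed,
split per stage, so identical configurations reproduce byte-identical
numeric outputs. The `analysis/` scripts in the repository are thin
narrative drivers over these functions; problem sizes there (a 24-residue
dimer, 5,000-frame ensembles, 10,000-draw distance series, 12-point
titrations) were chosen as the smallest sizes at which the estimators
reach the precision the analyses assert.

## Known limitations

* The toy dimer is a 24-residue surrogate; absolute CPL, SPM topology and
  Spearman coefficients of the real 416-residue system are not
  reproducible without the original trajectories, and the package makes
  no claim to them.
* Scalar-mode ensembles are isotropic by construction; anisotropic
  correlation structure only enters through `three_d` mode.
* KDE mode detection reports merged modes for components closer than the
  bandwidth; it does not deconvolve.
* The SPM edge threshold, contact definition and occupancy floor have no
  field-wide standard values; conclusions should be checked for
  robustness across these settings, which the configuration object makes
  cheap.
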