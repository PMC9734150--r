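# allonet

Allosteric communication networks and activation kinetics for ATP
phosphoribosyltransferase (ATPPRT).

ATPPRT, the first enzyme of histidine biosynthesis, is activated
allosterically: the regulatory subunit HisZ binds the catalytic HisGS
dimer far from the active site and constrains its conformational
dynamics, holding an arginine that reaches across the dimer interface in
a catalytic rotamer next to the pyrophosphate of PRPP. `allonet`
implements the two quantitative workflows behind that picture, for
structural-bioinformatics users who want to run them on their own
ensembles or on the built-in synthetic system:

* **Dynamics** — Kabsch superposition and RMSD; Cartesian PCA; dynamic
  cross-correlation matrices
  `C_ij = <Δr_i·Δr_j> / sqrt(<|Δr_i|²><|Δr_j|²>)` and their Spearman
  comparison; correlation-weighted residue graphs with edge length
  `-log|C_ij|`; shortest path maps (Dijkstra over all residue pairs,
  usage-normalized, threshold 0.3); characteristic path length (CPL) and
  node-weakening ΔCPL rankings; dynamical flexibility indices
  `DFI_i = Σ_j R_ij / Σ_kj R_kj` from analytic linear perturbation
  response; side-chain–ligand distance distributions with KDE mode
  detection.
* **Kinetics** — Michaelis–Menten saturation `v/E_T = k_cat·S/(K_M+S)`;
  thermal-melt sigmoid `F_U = LL + (UL−LL)/(1+e^{(T_m−T)/c})`; the
  tight-binding activation quadratic
  `v = V_max·(G+Z+K_D − √((G+Z+K_D)²−4GZ))/(2G)` with its companion
  complex-concentration expression; the Hill curve
  `v = V_max·Z^h/(K_0.5^h+Z^h)` (standard and as-printed forms);
  nonlinear least-squares fits with asymptotic standard errors; and the
  activation/impairment fold arithmetic.
* **Synthetic data** — an elastic-network ensemble generator (Gaussian /
  anisotropic network covariances, seed-deterministic sampling), a toy
  catalytic dimer whose regulator-bound variant stiffens the
  inter-subunit springs, bimodal distance series, and kinetic/melting
  dataset generators for all four models.

## Worked example

Titrate the catalytic subunit with its regulator under free-ligand
depletion, refit, and compare states of the toy dimer:

```r
library(allonet)

## kinetics: tight-binding titration at G = 0.42 uM, K_D = 0.44 uM
z <- seq(0, 5.1, length.out = 12)
dat <- simulate_rate_data("eq3", list(V_max = 1, G = 0.42, K_D = 0.44), z)
fit_binding(dat)
#> BindingFit: V_max = 1, K_D(app) = 0.44 +/- 4.8e-16 uM (G = 0.42 uM fixed)

fold_change(1.72, 0.0586, num_label = "WT holo k_cat", den_label = "WT alone")
#> WT holo k_cat / WT alone = 29.35 -> 29-fold

## dynamics: nonactivated vs regulator-bound toy dimer
apo   <- make_toy_dimer()
bound <- stiffen_intersubunit(apo, 5)
tr    <- sample_ensemble(network_covariance(bound, mode = "scalar"),
                         5000, seed = 1)
dccm  <- compute_dccm(tr, superpose = FALSE)
spm   <- compute_spm(build_residue_graph(tr, dccm))
spm
#> SpmResult: 19 / 65 edges in SPM (threshold 0.30, all pairs)

## bimodal catalytic/non-catalytic rotamer distances
s <- simulate_distance_series(c(4.4, 7.8), sigma = 0.3, n = 10000, seed = 1)
distance_distribution(s)
#> DistanceDistribution: n = 10000, bw = 0.246 A, modes at 4.39, 7.79 A
```

The fitted `K_D(app)` reproduces the generating constant of the
titration; the fold report carries both the exact ratio (29.35) and the
table-style integer fold; the regulator-bound dimer's shortest path map
includes inter-subunit edges that the loose-interface state lacks; and
the distance distribution recovers the two generating rotamer modes
within 0.1 Å.

The `analysis/` directory holds three narrative driver scripts —
`01_simulate_ensembles.R`, `02_dynamics_network.R`, `03_kinetics.R` —
that run both workflows end to end and write their tables under
`results/`.

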