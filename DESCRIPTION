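Package: allonet
Title: Allosteric Communication Networks and Activation Kinetics for ATP
    Phosphoribosyltransferase
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for allosteric communication in the
    hetero-octameric ATP phosphoribosyltransferase (HisGS/HisZ) system:
    elastic-network ensemble generation with a regulator-bound (interface
    stiffened) variant, Kabsch superposition and RMSD, Cartesian principal
    component analysis, dynamic cross-correlation matrices (DCCM) and their
    Spearman comparison, correlation-weighted residue graphs with shortest
    path maps (SPM), characteristic path length and node-weakening rankings,
    per-residue dynamical flexibility indices (DFI) from linear perturbation
    response, side-chain-ligand distance distributions with mode detection,
    and the enzyme kinetics toolbox for tight-binding activation titrations,
    Michaelis-Menten and Hill fits, thermal denaturation curves, and
    fold-activation arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    igraph,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
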