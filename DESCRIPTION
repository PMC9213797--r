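Package: idpbd
Title: Coarse-Grained Brownian Dynamics for Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bead-per-residue Brownian dynamics for intrinsically disordered
    proteins (IDPs). Provides CIDER-style sequence charge-pattern statistics
    (net charge per residue, fraction of charged residues, the charge
    segregation measure kappa, rescaled Kyte-Doolittle hydropathy, disorder
    fraction and Das-Pappu classification), chain construction from PQR/PDB
    structures or synthetic conformations, tabulated cubic-spline potentials
    with a global non-bonded scaling factor, Debye-Hueckel screened
    electrostatics, an overdamped (Ermak-McCammon) propagator with optional
    Rotne-Prager-Yamakawa hydrodynamic interactions and SHAKE-style bond
    constraints, structural and association observables (radius of gyration,
    Kirkwood hydrodynamic radius with linear calibration, inter-residue
    distance profiles, entanglement index, autocorrelation convergence
    checks), and a non-bonded scaling-factor scan against reference
    hydrodynamic radii.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    Biostrings,
    bio3d
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
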