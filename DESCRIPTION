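Package: hemeforge
Title: Coordination Force-Field Parametrization and Biased Sampling for
    Heme-Gas-Ligand Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building pair-specific Lennard-Jones (CHARMM
    NBFIX-style) coordination parameters for heme-gas-ligand complexes and
    for probing competitive CO/O2 binding with biased sampling. Fits
    coordination force curves extracted by baseline subtraction, inverts
    equilibrium-geometry and effective-potential features into a two-site
    Fe-O2 parameter set with a feedforward neural network, and runs steered
    pulling and well-tempered metadynamics on a reduced
    heme-imidazole-ligand model with a compiled Langevin engine. Includes a
    synthetic ground-truth generator standing in for quantum-chemistry
    reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
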