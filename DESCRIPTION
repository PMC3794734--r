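Package: amyloidtm
Title: Transfer-Matrix Statistical Mechanics of Amyloid Fibril Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium statistical mechanics of protein amyloid formation on
    one-dimensional and quasi-one-dimensional lattices. Provides Zimm-Bragg and
    zipper models for helix-coil transitions, Oosawa-Kasai mass-action
    aggregation, canonical transfer-matrix partition functions for filaments,
    protofibril strips and stacked-strip ("cube") fibrils, dilute multi-species
    ensembles with mass-balance solution of the fugacity, grand-canonical
    lattice-gas models with explicit solvent and a nucleation penalty,
    exhaustive-enumeration oracles for certification, and bounded least-squares
    fitting of sheet-fraction and mean-length concentration curves with
    synthetic-data generation for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
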