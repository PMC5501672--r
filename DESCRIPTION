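Package: porexlink
Title: Pore Profiling and Cysteine Cross-Link Compatibility Analysis for
    Ion-Channel Conformer Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for building confidence in alternative
    conformational models of ion channels such as CFTR. Computes probe-sphere
    pore radius profiles along the channel axis (HOLE-style simulated
    annealing), per-frame inter-residue C-beta distance statistics over
    conformer ensembles, bis-MTS cross-linker span-compatibility predictions
    reconciled against cysteine cross-linking observations, and structure or
    ensemble comparison: Kabsch superposition and RMSD, sequence-alignment
    guided cross-species correspondence, RMSD time-series equilibration
    detection, and quality-threshold conformational clustering. Includes a
    synthetic helix-bundle channel generator with analytic ground truth so
    every stage is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    withr
Config/testthat/edition: 3
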