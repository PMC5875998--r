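Package: hybridrank
Title: Hybrid NMR/MS2 Evidence Ranking for Metabolite Structure Elucidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating unknown LC-MS features by combining
    orthogonal evidence from accurate mass, tandem mass spectrometry and
    two-dimensional NMR. Starting from an accurate-mass feature, the
    package enumerates candidate elemental formulas and ranks them by
    isotope-pattern fit, ranks candidate structures by agreement between
    predicted and experimental 13C-1H HSQC peak lists (weighted
    chemical-shift distance and matching ratio), fragments candidate
    structures in silico for MS/MS spectrum annotation and scoring, and
    aggregates the NMR and MS/MS rankings into a consensus. Mixture
    samples are handled by deconvoluting the experimental HSQC into
    per-metabolite peak groups via TOCSY connectivity and scoring all
    candidate-by-group pairs. A seeded synthetic-scenario generator
    provides decoy-based benchmarks without any database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
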