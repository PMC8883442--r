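Package: kinarray
Title: Analysis of Human-Kinase Yeast-Array Phenotypic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotypic screens in which human protein kinases are
    expressed across arrayed yeast strains and colony growth is scored on an
    ordinal 0-3 scale over many stress conditions. Provides readers for long
    and plate-grid score tables, clone-to-kinase aggregation, count-based
    condition quality control with bimodal valley detection, per-strain
    activity binning and hierarchical activity tiering, cross-strain
    concordance (upset counts and severe-defect histograms), rank-sum group
    comparisons, differential phospho-dependent two-hybrid interaction
    calling from dilution-series growth, logistic growth-curve fitting for
    wild-type versus kinase-dead comparisons, and a synthetic-screen
    generator with planted truth so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
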