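Package: gsimpop
Title: Genomic Selection in Intermated Biparental Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genomic selection in
    intermated biparental (IBM-style) maize populations. Simulates
    recombinant inbred line and doubled haploid populations derived from a
    biparental cross with several generations of intermating, together with
    additive quantitative traits and replicated plot phenotypes. Provides
    hidden-Markov-model imputation of missing genotypes and nearest-flanking-
    marker cross-panel imputation, linkage-disequilibrium (r2) decay curves
    and adjacent-marker LD, realized (identity-by-state) kinship, expanded
    genetic-map estimation, ridge-regression BLUP (RR-BLUP) of marker
    effects with primal and dual solvers, and a cross-validation engine
    running training-size by marker-density grids over seven
    training/validation scenarios with Bonferroni-adjusted least significant
    differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
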