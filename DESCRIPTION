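Package: batchtree
Title: Hierarchical Batch-Effect Correction Trees for Incomplete Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Missing-value tolerant integration of many feature-by-sample
    omics datasets (proteomics, metabolomics, transcriptomics) by arranging
    pairwise batch-effect correction steps in a binary tree. Each pairwise
    step applies either an empirical-Bayes location/scale adjustment or a
    linear-model correction, both aware of categorical covariates, with an
    additional reference-sample mode for designs where biological conditions
    are known only for a subset of samples. Features lacking sufficient
    numeric data in a pair of batches are propagated unchanged, so no values
    are lost after an initial singleton-removal pre-processing pass. Includes
    a generative simulator for multi-batch data with configurable
    missingness and class imbalance, average-silhouette-width quality
    metrics tolerant of missing entries, and scripted desk-scale experiments.
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
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs
Suggests:
    cluster,
    limma,
    optparse,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
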