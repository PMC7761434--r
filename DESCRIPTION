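Package: wcmfe
Title: Weighted Composite Multiscale Fuzzy Entropy for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Entropy-based feature extraction for two-class motor-imagery
    electroencephalography (MI-EEG). Implements fuzzy entropy, composite
    multiscale fuzzy entropy (CMFE) and its weighted variant (WCMFE), in
    which the coarse-graining step uses symmetric linear-phase weighted-mean
    filters instead of plain moving averages. Includes trial cropping and
    interval selection, multi-channel multi-scale feature fusion, a
    synthetic ERD/ERS-style MI-EEG generator, a small back-propagation
    network classifier under repeated stratified k-fold cross-validation,
    and the accompanying statistical comparison chain (Lilliefors
    normality, variance homogeneity, pooled two-sample t-test).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
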