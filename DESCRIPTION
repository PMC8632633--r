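Package: qeegamyloid
Title: Quantitative EEG Band-Power Features and Generational Feature
    Search for Amyloid-Status Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting brain amyloid status in
    pre-dementia patients (subjective cognitive decline and mild cognitive
    impairment) from resting-state eyes-closed EEG. Implements relative
    band-power feature extraction (19 channels of the International 10-20
    montage by eight frequency bands, Welch spectra at 0.25 Hz resolution),
    stratified holdout with split-half augmentation of the minority class,
    univariate group screening, a generational combinatorial feature search
    that exhaustively scores low-dimensional feature combinations and
    propagates the features recurring in the best models to
    higher-dimensional generations, and a multi-sub-model voting ensemble
    with cutoff classification and confusion-matrix evaluation. Includes a
    synthetic cohort generator emulating the group spectral differences the
    analysis assumes, so the whole pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    withr
Config/testthat/edition: 3
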