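Package: sbpseg
Title: Stationarity Segmentation and Apnea Screening from Beat-to-Beat Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric segmentation of beat-to-beat systolic blood
    pressure series into stationarity patches via recursive binary splitting
    at the maximal two-sample Kolmogorov-Smirnov distance, with Monte-Carlo
    calibrated significance thresholds.  Derives per-subject apnea
    quantifiers from the segmentation (mean patch length, mean patch
    variance, and the normalized spectral peak of the local-mean-detrended
    signal), compares groups with two-sample Kolmogorov-Smirnov tests, and
    screens for sleep apnea with ROC threshold analysis and a combined
    two-feature decision rule.  Includes a synthetic cohort generator that
    emulates piecewise-stationary blood pressure baselines and apneic
    oscillatory epochs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
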