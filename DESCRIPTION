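Package: sleepstager
Title: Interpretable Sleep Stage Classification from EEG and EOG Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interpretable, classical machine-learning pipeline for automatic
    sleep staging of 30-second polysomnography epochs into the five stages
    W/N1/N2/N3/REM. Reads EDF/EDF+ recordings (one EEG and one horizontal EOG
    channel) with hypnogram annotations, denoises epochs by db4 wavelet soft
    thresholding, decomposes the EEG into the seven classical rhythm bands with
    Kaiser-window FIR filters, and extracts a canonical 76-column multi-domain
    feature matrix: per-band time-domain statistics, Yule-Walker spectral
    band-power ratios, multiscale sample entropy, and two electrooculogram
    features built on large-eye-movement detection. Features are screened by a
    Fisher-score prefilter followed by gradient-boosted-tree importance ranking,
    and classified with XGBoost under subject-wise cross-validation. Includes a
    synthetic polysomnography generator with stage-dependent spectral profiles
    and planted eye-movement events so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    caret,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
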