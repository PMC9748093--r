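Package: ctgdffn
Title: Deep Feature Fusion for Intrapartum Fetal Heart Rate Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for computer-aided fetal state assessment from 4 Hz
    cardiotocographic fetal heart rate (FHR) recordings. Implements the full
    pipeline: signal preprocessing (invalid-sample rules, linear interpolation,
    record quality gates), a 16-dimensional engineered feature bank (FIGO-style
    morphological features, time-domain and heart-rate-variability statistics,
    approximate/sample entropy and Lempel-Ziv complexity), a multiscale
    CNN-BiLSTM backbone trained with class-weighted cross-entropy, a two-stage
    deep feature fusion classifier, a stratified cross-validation harness
    reporting sensitivity/specificity/quality-index, and a class-conditional
    synthetic FHR generator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
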