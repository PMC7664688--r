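Package: eegintent
Title: Subject-Wise EEG Classification of Malicious Intention and Scenario Type
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, feature engineering and subject-wise
    evaluation pipeline for detecting implicit malicious intention from
    multichannel EEG. Generates seeded synthetic 21-channel recordings with
    1/f background, band-limited oscillations and configurable
    class-conditional effects; cleans and epochs them (resampling, zero-phase
    high-pass and notch filtering, bad-channel interpolation, average
    re-reference); extracts a 65-feature-per-channel catalogue spanning time,
    wavelet, spectral and nonlinear domains; selects features on training
    folds with Boruta-style shadow testing and varSelRF-style backward
    elimination over a built-in random forest; and evaluates
    leave-one-question-out, per-subject, with tuned kNN, RBF-SVM, Gaussian
    naive Bayes and MLP classifiers aggregated by epoch majority vote.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    FNN
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
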