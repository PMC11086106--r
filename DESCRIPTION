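Package: seizcal
Title: Patient-Independent Seizure Forecasting with Model Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for forecasting epileptic seizures from long-term
    multichannel scalp EEG. Reads EDF recordings with seizure annotations,
    labels preictal and interictal segments under eligibility rules that
    enforce a four-hour separation between the two states, preprocesses and
    windows the signal under leakage-aware standardization protocols, and
    classifies 5-second windows with either a six-block convolutional neural
    network trained on the raw signal or a gradient-boosted baseline on 53
    engineered features. Supports randomized cross-validation, leave-one-
    patient-out validation, and calibration of the patient-independent model
    by fine-tuning on one or two seizures from the target patient, with
    repeated-measures ANOVA and Tukey post hoc evaluation statistics. A
    synthetic EEG cohort generator with per-patient spectral signatures makes
    every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    xgboost,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
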