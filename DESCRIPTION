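Package: macerisk
Title: Machine Learning Risk Scoring for Major Adverse Cardiac Events from
    Heart Rate Variability and Vital Signs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for short-term risk stratification of emergency department
    chest pain patients. Computes time-domain, geometric and frequency-domain
    heart rate variability (HRV) parameters from short RR-interval recordings;
    selects predictive variables on heavily imbalanced cohorts with an
    ensemble of random forests fitted to repeated balanced subsamples; fits a
    geometric distance-based 0-100 risk score refined by a calibrated support
    vector machine; derives TIMI, MEWS and forward-selection logistic
    comparator scores; and evaluates models with leave-one-out
    cross-validation, ROC/AUC analysis with DeLong or bootstrap confidence
    intervals, upper-left-corner cutoff selection and paired bootstrap AUC
    comparison. Includes a synthetic cohort generator reproducing published
    group-conditional summary statistics so the full pipeline can be exercised
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    randomForest,
    e1071,
    pROC,
    jsonlite,
    yaml
Suggests:
    glmnet,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
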