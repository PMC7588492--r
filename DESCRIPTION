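Package: akirisk
Title: Real-Time Prediction of Postoperative Acute Kidney Injury from EHR Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-data-testable pipeline for real-time
    prediction of severe postoperative acute kidney injury (KDIGO stage 2/3)
    from irregular electronic-health-record streams. Provides a seeded
    synthetic EHR cohort generator; KDIGO stage-2/3 labeling from serum
    creatinine and weight-normalised urine output with observation windows,
    exclusion rules and case-control matching on observation length; 15-minute
    feature-grid preprocessing (forward/default imputation, robust
    median/IQR scaling, single-slice drug-event encoding, bag-of-words
    surgery-text models); a small recurrent risk model (GRU or tanh cells,
    Adam, per-step cross-entropy) with five-fold cross-validation, a uniform
    ensemble and sensitivity-targeted threshold calibration; and a clustered
    evaluation toolkit (per-patient Brier scores, design-effect confidence
    intervals via the intracluster correlation, Hosmer-Lemeshow calibration,
    DeLong and paired-t comparisons, quasi-random prediction-point sampling
    and time-to-event stratified reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    glmnet,
    Matrix,
    pROC,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
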