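Package: psgcomorb
Title: Multi-Label Comorbidity Identification from Overnight SpO2 and Nasal Airflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for identifying obstructive sleep apnea (OSA)
    comorbidities (hypertension, diabetes mellitus, asthma/COPD) from overnight
    pulse-oximetry (SpO2) and nasal-airflow (FP0) recordings fused with clinical
    variables. Provides a synthetic polysomnography cohort simulator with known
    ground-truth event markers, EDF and Feather I/O, signal preprocessing
    (resampling, artifact repair, low-pass/moving-average/Savitzky-Golay
    filtering, windowing), apnea-desaturation event detection and pairing with
    engineered timing and morphology features, cohort group comparisons
    (one-sided Welch tests, Cohen's d), a multi-branch one-dimensional
    convolutional neural network with a three-unit sigmoid multi-label head
    trained under class-weighted binary cross-entropy or focal loss, and a
    complete multi-label evaluation suite including the fractional multi-label
    confusion matrix with derived precision and recall matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
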