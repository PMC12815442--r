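Package: wase
Title: Composite Biomechanical Injury-Risk Scoring and Simulation-Based
    Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the WASe composite biomechanical injury-risk score,
    a weighted combination of four gait-level instability indices (force
    variability, temporal asymmetry, load distribution, bilateral asymmetry)
    with an optional critical-transitions convergence factor, together with
    the complete Monte-Carlo validation study around it: a virtual-cohort
    generator with correlated truncated-normal components and multiplicative
    measurement noise, a logistic injury linkage calibrated jointly to a
    target incidence and a target expected AUC, and a diagnostic-evaluation
    battery (ROC/AUC with midrank tie handling, Youden thresholding,
    stratified percentile-bootstrap confidence intervals, unpaired DeLong
    AUC comparison, Hosmer-Lemeshow calibration, stratified k-fold
    cross-validation, subgroup analysis, and weight-sensitivity analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
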