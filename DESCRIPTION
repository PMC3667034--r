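Package: hbdonor
Title: Transition and Mixed-Effects Models for Dynamic Prediction of
    Hemoglobin in Blood Donors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamically predicting hemoglobin (Hb) levels and
    donation eligibility in whole-blood donors from unbalanced longitudinal
    (panel) visit data.  Implements covariate-adjusted autoregressive
    transition models of order q estimated by the exact Gaussian likelihood
    with stationary initialization, linear mixed-effects models (random
    intercept, random intercept plus age slope) estimated by restricted
    maximum likelihood with empirical-Bayes dynamic prediction, a multiple
    linear regression benchmark, visit-wise mean squared prediction error,
    ROC/AUC analysis of deferral prediction at the clinical eligibility
    cut-offs (8.4 mmol/l men, 7.8 mmol/l women), paired bootstrap AUC
    comparison, and a synthetic-cohort generator with endogenous
    donation feedback for testing every stage without donor-registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    pROC,
    withr
Config/testthat/edition: 3
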