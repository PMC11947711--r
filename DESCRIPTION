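Package: coras
Title: Collaborative Respiratory Assessment Score for Post-Stroke Pneumonia Risk
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the Collaborative Respiratory Assessment Score (CoRAS),
    an eight-parameter, 100-point admission score for stratifying pneumonia
    risk among stroke patients in convalescent (Kaifukuki) rehabilitation
    wards, together with the statistical validation pipeline used to assess
    it: univariate contingency and rank tests, inter-parameter correlation
    and variance-inflation diagnostics, adjusted logistic regression with
    Wald confidence intervals, and ROC/AUC model comparison with DeLong
    confidence intervals and likelihood-ratio tests. A Gaussian-copula
    synthetic-cohort generator reproduces the published cohort's marginal
    distributions, inter-parameter correlation structure, and score-outcome
    effect so that every stage of the pipeline can be exercised and tested
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    car,
    yaml
Config/testthat/edition: 3
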