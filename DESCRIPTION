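Package: postrosc
Title: Decision and Outcome Modeling for Out-of-Hospital Cardiac Arrest Registries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models post-resuscitation hospital decisions and neurologic
    outcomes from categorical cardiac-arrest registry data. Provides an
    embedded fully convolutional network (EFCN) classifier pair in which
    per-feature embedding tables learned for the coronary-angiography
    decision task are transferred to the downstream neurologic-outcome
    task, a grid-searched classical-model comparison harness, evaluation
    metrics (AUROC, AUPRC, F1, MCC, Brier, Shapley-style attributions),
    hospital-cohort stratification by functional-outcome rate, and a
    counterfactual audit that re-scores lower-tertile hospitals' patients
    under the top tertile's decision policy. A calibrated synthetic
    registry generator with hospital-level heterogeneity makes the full
    pipeline testable without restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost,
    randomForest,
    rpart,
    nnet,
    class,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
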