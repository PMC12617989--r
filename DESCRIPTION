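Package: gapbench
Title: Benchmarking Missing-Data Handling for Longitudinal Clinical Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Experimental machinery for evaluating missing-data strategies in
    electronic-health-record-based clinical prediction. Generates synthetic
    intensive-care cohorts with controlled temporal autocorrelation, collapses
    raw observations into 4-hour windows with lagged wide features, constructs
    a fully observed reference table, induces missingness under MCAR, MAR and
    graded MNAR mechanisms at controlled cell-wise proportions, applies six
    transferable strategies for handling missing values (mean, last observation
    carried forward, random-forest donor sampling, Bayesian predictive mean
    matching, bootstrap-LASSO, and native missing-value support) under a strict
    fit-on-train / apply-to-new-rows contract, fits gradient boosted tree and
    L1-penalized outcome models, and evaluates both imputation accuracy
    (standardized mean squared error, classification error) and prediction
    performance (balanced accuracy, AUC, and related metrics).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    zoo,
    ranger,
    glmnet,
    rpart,
    xgboost,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
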