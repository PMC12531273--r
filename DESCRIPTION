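Package: cohortcapture
Title: Multi-Database Capture-Recapture Estimation of Clinical Cohort Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the total size of a disease cohort fragmented across
    many partially overlapping clinical databases. Implements a recursive
    Jaccard-similarity capture-recapture protocol over precision-ranked
    databases, per-database diagnostic-accuracy profiling with bootstrap
    confidence intervals, regex-based free-text concept flagging with synonym
    normalization, elastic-net penalized logistic-regression cohort
    classification with nested cross-validation, Platt calibration and
    threshold sweeps, stratified fairness auditing, and the Pate-Riley
    minimum sample-size formula for binary prediction models. Ships a seeded
    synthetic multi-database electronic health record generator so the whole
    pipeline can be exercised end to end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    pROC,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
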