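Package: dweml
Title: Double-Weighted Ensemble Machine Learning for Metabolomics Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of metabolomics feature tables with a
    double-weighted ensemble of nine base classifier families. Provides
    metabolomics pretreatment recipes (total-area normalization, log10
    transformation, autoscaling, Pareto scaling), SMOTE augmentation to a
    minimum cohort size with class-imbalance control, stratified
    cross-validation of the base learners with an accuracy gate, a signed
    voting combiner weighting each vote by cross-validation accuracy and
    per-sample classification confidence, ROC analysis with Youden-optimal
    cutoff selection, grid-search hyperparameter optimization, genetic-
    algorithm wrapper feature selection, a label-permutation overfitting
    check, and a synthetic wide-short two-class data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    glmnet,
    nnet,
    rpart,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
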