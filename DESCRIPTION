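Package: sdml
Title: Small-Data Machine Learning for Root Concentration Factors of PFASs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small-data machine-learning workflow for predicting the log10
    root concentration factor (log RCF) of per- and polyfluoroalkyl substances
    (PFASs) in hydroponic plants from molecular descriptors and exposure
    covariates. Provides preprocessing (random-forest iterative imputation,
    1.5-IQR target trimming, skewness-driven log transforms), composite
    multi-statistic feature scoring (F-statistic, mutual information, distance
    correlation, maximal information coefficient, ReliefF, bootstrap stability,
    VIF penalty), stratified dual-pipeline data augmentation for regression
    (adaptive target binning, SMOTER interpolation and a variational
    autoencoder under iterative quality control), gradient-boosted tree models
    with tree-structured Parzen estimator hyperparameter search, tiered
    Shapley-value model explanation, three symbolic-regression engines that
    emit explicit predictive equations, and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    pracma,
    ranger,
    withr,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
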