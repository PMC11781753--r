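Package: cmcisway
Title: Composite Multiscale Complexity Analysis of Postural Sway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the complexity of center-of-pressure (CoP)
    balance recordings. Implements empirical mode decomposition with
    energy-based mode truncation, Hilbert analytic-signal amplitude and phase
    extraction, sample entropy, and the Composite Multiscale Complexity Index
    (CMCI) that averages the equally weighted amplitude- and phase-entropies
    over retained intrinsic mode functions. Also provides classical
    stabilogram descriptors (CoP path length, tilt angle), time-domain and
    CMCI feature tables, a classification bench (bagged ranking forest,
    naive Bayes, regularized logistic regression, SVM) with stratified
    splits, ROC/AUC evaluation and cross-validation, normality-gated group
    comparisons, and a seeded synthetic stabilogram generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nortest,
    purrr,
    Rcpp,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
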