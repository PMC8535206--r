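Package: rankstab
Title: Stability and Predictive Power of Feature Rankings in Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint evaluation of feature-ranking stability and predictive
    performance for case-control risk prediction. Six feature rankers
    (ReliefF, point-biserial Pearson, SVM and logistic-regression wrappers,
    SVM recursive feature elimination, random forests) are run repeatedly on
    random subsamples of a cohort; the resulting rank lists are compared with
    averaged pairwise Spearman rank correlation, Jaccard top-k overlap curves
    and a multidimensional-scaling projection, while predictive power is
    measured as cross-validated AUC of five classifiers over nested top-k
    feature subsets. A seeded synthetic case-control generator with
    Hardy-Weinberg genotypes, block-correlated environmental exposures and a
    weak-signal logistic disease model makes the whole pipeline runnable
    without access to any cohort data.
License: MIT
Encoding: UTF-8
Imports:
    caret,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
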