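Package: fsstab
Title: Feature-Selection Stability and Accuracy in Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for benchmarking SNP feature-selection
    methods in genomic prediction of quantitative traits such as residual
    feed intake. Provides phenotype pre-adjustment (metabolic weight,
    Mahalanobis outlier screening, residual-feed-intake derivation and
    environmental adjustment), genotype quality control (call rate, minor
    allele frequency, near-zero variance, correlation pruning), five filter
    feature selectors (Spearman correlation, univariate decision tree,
    maximum-relevance-minimum-redundancy, conditional permutation
    importance, random benchmark), penalized regression, support vector
    machine, gradient boosting and Bayesian GBLUP learners, nested
    cross-validation orchestration, and chance-corrected feature-selection
    stability estimation with confidence intervals, plus a synthetic SNP
    data generator so the whole pipeline is testable without proprietary
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    xgboost,
    ranger,
    rpart,
    caret,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
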