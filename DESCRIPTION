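Package: dilimark
Title: Ensemble-Weighted Biomarker Discovery for Drug-Induced Liver Injury Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for transcriptomic biomarker discovery in
    two-group (case/control) microarray cohorts, modelled on drug-induced
    liver injury (DILI) studies. Provides quantile normalization and
    location/scale batch adjustment, a seeded stratified train/test split,
    moderated-t differential expression with logFC/FDR/p filtering, six
    classifier importance extractors (lasso, linear SVM, decision tree,
    random forest, gradient boosting, neural network), max-normalized
    overall-weight aggregation with threshold selection, ROC/AUC and
    immune-cell correlation evaluation, gene-set over-representation and
    GSEA running-sum statistics, and a synthetic microarray generator with
    planted effects so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    glmnet,
    e1071,
    rpart,
    randomForest,
    xgboost,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
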