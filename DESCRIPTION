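Package: ifsmarker
Title: Incremental Feature Selection and Rule Extraction for Labeled Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable marker-discovery pipeline for labeled (cell x gene)
    expression matrices with imbalanced classes. Eight feature-importance
    rankers (including a from-scratch Monte Carlo feature selection, an
    oblivious-tree gradient booster and multiclass AdaBoost) produce ordered
    gene lists; incremental feature selection sweeps nested list prefixes with
    SMOTE-balanced stratified cross-validation under decision-tree and
    random-forest classifiers; essential feature subsets are extracted at
    curve maxima or earlier "relatively high" points, intersected across
    rankers into a consensus table, and a final decision tree is converted
    into human-readable threshold rules per class. Includes a synthetic
    single-cell-style expression generator with planted class markers for
    ground-truth validation, and readers/writers for CSV/TSV and MatrixMarket
    matrices, feature lists, IFS curves and rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    glmnet,
    jsonlite,
    ranger,
    rpart,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
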