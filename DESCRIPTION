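Package: citescreen
Title: Class-Imbalance Strategies for Machine-Learning Citation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates machine-learning strategies for screening bibliographic
    citations (title + abstract) for inclusion in systematic reviews under
    extreme class imbalance. Provides text preprocessing into sparse
    document-term matrices (lowercasing, Porter stemming, bigrams), fold-wise
    TF-IDF weighting with top-fraction token retention, random over- and
    undersampling to 50:50 and 35:65 minority:majority ratios inside
    stratified cross-validation, AUC-ROC evaluation of four classifier
    families (support vector machine, k-nearest neighbour, random forest,
    elastic-net logistic regression) with random hyperparameter search, and
    fixed-effect meta-analytic pooling of per-review delta-AUCs with forest
    plots. A synthetic-corpus generator with a controllable class-separation
    dial emulates imbalanced PubMed-style screening corpora so the whole
    pipeline is testable without live database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    e1071,
    class,
    ranger,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    withr
Config/testthat/edition: 3
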