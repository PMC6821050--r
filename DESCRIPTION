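Package: eglink
Title: Supervised Prediction of Enhancer-Gene Interactions from Activity and Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts tissue- and cell-type-specific enhancer-gene interactions
    from six features derived solely from enhancer annotation and gene
    expression: the enhancer-activity/gene-expression correlation across a
    multi-cell-type panel (EGC), the target gene's expression (GS), the
    enhancer-TSS genomic distance (DIS), distance-normalized enhancer and gene
    window signals between the pair (EWS, GWS), and the mean correlation of an
    enhancer with the other enhancers near the gene (WEEC). Candidate pairs
    within 1 Mbp are labeled against ChIA-PET- or Hi-C-style loop anchors
    (BEDPE), a balanced AdaBoost ensemble of shallow decision trees is trained
    on the labeled feature vectors, and performance is assessed by AUROC/AUPR
    under self-test and cross-sample protocols with permutation feature
    importance. A seeded synthetic-data generator emulates the multi-cell-type
    activity/expression structure of real loop data so the whole pipeline runs
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
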