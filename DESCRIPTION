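Package: mndesign
Title: Machine-Learning Design and Ranking of Engineered Meganuclease Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for engineering I-CreI homing-endonuclease (meganuclease)
    variants against new 22 bp pseudopalindromic DNA targets. Implements the
    target coordinate system and region decomposition (2N4/5N3/7N2/11N4), the
    combinatorial module-assembly screening process with positive-only
    sequencing, categorical/one-hot/pairwise-interaction feature encodings of
    protein-DNA pairs, penalized-logistic (LASSO) and gradient-boosted-tree
    learners combined into a rank-ensemble scorer, per-target ranking metrics
    (AUC, TopN, %TopN) with target-level cross-validation, learning curves and
    distance-constrained training subsampling, specificity profiles with an
    activity/specificity trade-off ranking, and a calibrated synthetic
    screening simulator with planted mutation and interaction effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    xgboost,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
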