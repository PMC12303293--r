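Package: dermastack
Title: Hybrid Image and Clinical-Metadata Stacking for Smartphone Skin-Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a hybrid six-class skin-lesion classifier for smartphone
    photographs paired with clinical metadata. Images are enhanced with a
    morphological Black-Hat transform and adaptive Gaussian thresholding, the
    (original, Black-Hat, adaptive) triplet is passed through a patch-based
    transformer feature extractor, branch feature maps are fused by element-wise
    multiplication and width-axis concatenation, and a global-average-pooled
    softmax head trained with class-weighted focal loss produces image-branch
    probabilities. A gradient-boosted model on the clinical-metadata table
    (PAD-UFES-20 schema) produces a second probability vector, and the two are
    combined by out-of-fold stacking with a ridge multinomial logistic-regression
    meta-model. Includes stratified cross-validation utilities, per-class and
    macro PPV/recall/F1/NPV evaluation arithmetic, and a seeded generator of
    lesion-like synthetic images and metadata for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jpeg,
    xgboost,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
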