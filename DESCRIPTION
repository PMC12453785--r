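Package: mammopatch
Title: Patch-Based Mammogram Phantom Classification with Hybrid Features and
    Swarm-Tuned Progressive Cyclical Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for patch-wise analysis of grayscale breast images:
    seeded synthetic phantom generation with ground-truth lesion masks,
    preprocessing (resizing, normalization, CLAHE contrast enhancement,
    augmentation, feature standardization, stratified splitting), sliding
    window patch extraction with majority-region labeling, hybrid feature
    extraction (local binary pattern histograms, Hu moment invariants,
    Canny edge statistics, and pooled activations of a convolutional
    backbone) with feature fusion, progressive staged training under a
    cyclical (cosine-restart) learning-rate schedule, firefly-style swarm
    hyperparameter optimization, and a full evaluation stack (confusion
    matrices, ROC-AUC, calibration curves, cross-validation with bootstrap
    confidence intervals).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
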