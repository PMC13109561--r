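Package: varietyid
Title: Image-Based Crop Variety Identification with Spatiotemporal Mixed
    Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fine-grained identification of crop varieties (accessions,
    inbred lines) from whole-plant RGB images captured across growth
    stages and viewpoints. Provides filename-encoded dataset parsing and
    stratified splitting, growth-stage and multi-view mixed augmentation
    (convex interpolation of same-accession image pairs along temporal,
    viewpoint and view-stage axes), a small convolutional network trained
    by stochastic gradient descent with either standard or adaptive
    (hard-example weighted) cross-entropy loss, macro-averaged evaluation
    metrics with per-stage and within/between-group confusion breakdowns,
    gradient-weighted class activation maps for interpretability, a
    handcrafted-feature baseline (Hu moments, co-occurrence contrast,
    uniform local binary patterns, HSV means) with four classical
    classifiers, and a deterministic synthetic plant-image generator for
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    e1071,
    rpart,
    class,
    stats,
    grDevices,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
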