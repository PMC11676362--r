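Package: cytoscreen
Title: Distribution-Augmented Contrastive One-Class Screening for Cervical Cytology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-class screening pipeline for cervical cytology tiles.
    An encoder is pretrained with contrastive self-supervised learning
    (NT-Xent) on normal-only tiles, optionally expanding the training
    distribution with hue-interval or right-angle-rotation copies
    (distribution augmentation). Frozen embeddings are scored for
    abnormality with density-based one-class models (Gaussian kernel
    density estimation, one-class support vector machines, Gaussian
    mixtures), aggregated to slide level, and abnormal cells are
    localized with a GradCAM attention map driven by the differentiable
    kernel-density anomaly score. Includes tile preprocessing (grid
    tiling, background exclusion, box-based labeling, class balancing,
    grouped cross-validation folds) and a seeded synthetic cytology tile
    generator for end-to-end testing without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    jsonlite,
    e1071,
    mclust,
    nnet
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
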