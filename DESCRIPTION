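Package: pestaug
Title: Manipulation-Based Data Augmentation for Insect Pest Image
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a manipulation-based data augmentation (MBDA)
    framework for small labeled insect-pest image datasets. Provides
    label-preserving atomic transforms (center rotation, flips, Gaussian
    noise injection, per-channel histogram equalization, central-crop
    scaling, same-class mixup, and fancy-PCA intensity perturbation), a
    cascaded augmentation pipeline that expands each source image into a
    fixed number of derived images, eleven named benchmark augmentation
    strategies, image-folder input/output with provenance manifests,
    stratified train/validation splitting, a seeded synthetic pest-image
    generator for fully reproducible experiments, and a desk-scale
    transfer-learning evaluation harness (frozen feature backbone plus a
    trainable 512-unit dense head) that measures each strategy's
    contribution to validation accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
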