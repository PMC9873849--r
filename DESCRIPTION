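Package: camloc
Title: Weakly-Supervised Classification and Localization of Lesions with
    Class Activation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-label classification and weakly-supervised lesion
    localization for grayscale radiographs using class activation maps
    (CAMs). Implements a multi-resolution CNN backbone with merge blocks
    that re-fuse early high-resolution features into the coarse output,
    log-sum-exp (LSE) pooled per-pixel classification, a pixel correlation
    module (PCM) that refines CAMs by normalized-cosine self-attention
    over backbone features, dynamically class-balanced binary
    cross-entropy, and Siamese equivariant training of the PCM with
    equivariant cross regularization and online hard example mining.
    Includes a synthetic radiograph generator emulating the NIH
    ChestX-ray14 directory layout, the standard preprocessing and
    augmentation policy, and the IoBB-based localization evaluation
    protocol (localization accuracy and average false-positive number).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    png,
    pROC,
    tibble,
    dplyr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
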