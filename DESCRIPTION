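Package: leafgan
Title: Label-Smoothed Wasserstein GAN Augmentation for Limited-Data Plant
    Disease Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Trains a conditional Wasserstein generative adversarial network
    with gradient penalty whose auxiliary class head uses label smoothing
    regularization (WGAN-GP-LSR), and uses it to synthesize labeled leaf
    images that enlarge small training sets for convolutional plant-disease
    classifiers. Implements the classic augmentation pipeline (rotation,
    shift, zoom, flips, photometric jitter), a VGG16-style classifier, the
    four-regime comparison protocol (real only; classic augmentation;
    augmentation plus WGAN-GP synthesis; augmentation plus WGAN-GP-LSR
    synthesis), and multiclass evaluation (confusion matrix, per-class
    recall/precision/F1, macro averages). A deterministic procedural
    leaf-image generator provides class-separable fixtures so the whole
    pipeline runs without downloads. All network layers and their gradients,
    including the exact input-gradient penalty for piecewise-linear critics,
    are implemented in the package with Rcpp kernels for the convolution and
    pooling hot paths.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret,
    MASS,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
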