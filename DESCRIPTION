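Package: dilatedskinnet
Title: Atrous Convolutional Network for Dermoscopic Skin Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A from-scratch implementation of DilatedSkinNet, a 16-layer
    atrous (dilated) convolutional neural network for binary semantic
    segmentation of dermoscopic skin-lesion images. Provides reference
    implementations of the numerical primitives (dilated convolution,
    batch normalization, leaky rectified linear activation, weighted
    cross-entropy loss, stochastic gradient descent with momentum), the
    published layer architecture encoded as data with structural checks
    (output shapes, learnable-parameter counts, receptive field), pixel
    confusion-matrix metrics (accuracy, Jaccard index, Dice coefficient),
    a synthetic dermoscopic-phantom generator with ground-truth masks and
    artifact overlays (hairlines, gel bubbles, illumination gradients,
    low contrast), and an end-to-end training and evaluation pipeline
    with a command-line interface, so the full method is buildable and
    testable without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
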