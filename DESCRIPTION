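Package: vesselseg
Title: Multi-Scale Feature-Fusion Encoder-Decoder Networks for Retinal
    Vessel Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for per-pixel segmentation of retinal blood vessels in
    fundus photographs. Implements a multi-scale feature-fusion U-Net
    (inception-style multi-scale encoder blocks, max-pooling index unpooling
    in the decoder, dual skip connections) together with a classic U-Net
    baseline, a cost-sensitive Dice plus cross-entropy training objective,
    contrast-limited adaptive histogram equalization (CLAHE) preprocessing,
    paired image/mask augmentation, pixel-classification metrics (sensitivity,
    specificity, accuracy, ROC/AUC), and a synthetic vessel-phantom generator
    so the whole pipeline is exercisable without clinical data. Networks are
    trained by stochastic gradient descent on a compact CNN engine built on
    'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
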