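Package: ultraseg
Title: Residual Attention U-Net for Breast Ultrasound Tumor Segmentation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds, trains and evaluates a residual U-Net for segmenting
    hypoechoic tumor regions in grayscale breast ultrasound images. Skip
    connections are gated by a positional convolutional block attention
    module (channel attention, dilated spatial attention and softmax
    position attention fused additively) and the bottleneck carries a
    projection-based global attention block with a residual connection.
    The forward and backward passes of every layer (convolution, batch
    normalization, transposed convolution, the attention blocks and the
    compound Dice + binary cross-entropy + focal objective) are implemented
    directly on top of R's linear algebra, so the package runs on a plain
    CPU without an external deep-learning runtime. A synthetic
    speckled-phantom generator, a BUSI-layout PNG loader, dataset splitting
    utilities, a segmentation metric suite, heatmap export and a
    command-line interface round out the toolchain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
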