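Package: rtcbnet
Title: Attention-Augmented Partial-Convolution ResNet18 for Leaf Disease
    Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, trains, profiles and exports modified ResNet18 image
    classifiers for five-class garlic leaf disease recognition (botrytis,
    rust, blight, purple spot, healthy). Provides triplet attention
    (Z-pool over three rotated branches), the convolutional block
    attention module (CBAM), and partial convolution (PConv) layers with
    exact multiply-accumulate accounting; a deterministic synthetic leaf
    image generator; stratified 3:1:1 dataset splitting; robustness
    augmentations; a seeded cosine-annealed training loop; confusion-table
    metrics; and a portable graph export format with an independent
    interpreter for parity checking. The numeric core (convolution
    forward/backward, pooling, batch normalisation and a small
    reverse-mode tape) is implemented in C++ via Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
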