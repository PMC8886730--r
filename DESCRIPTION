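Package: medusa
Title: Multi-Scale Encoder-Decoder Self-Attention for Medical Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a "single body, multi-scale heads" self-attention
    mechanism for convolutional image classifiers: a U-Net-style
    encoder-decoder produces one global attention map over the input
    image, which is bounded by a logistic, bilinearly resized and
    projected by per-scale convolutions into local attention maps that
    gate the backbone's feature maps through residual multiplicative
    attention. Includes segmentation pretraining of the encoder-decoder,
    alternating freeze/train optimization of the attention block versus
    the main network, ablation modes, confusion-matrix metrics
    (sensitivity, positive predictive value, accuracy), attention
    heat-map visualizations, and a deterministic synthetic lung-phantom
    generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    tools,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    EBImage
Config/testthat/edition: 3
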