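Package: ConnSegNets
Title: Connected SegNet Networks for Breast Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A CPU implementation of the Connected-SegNets architecture for
    breast tumor segmentation from mammographic regions of interest: two
    SegNet encoder-decoder networks whose decoders upsample with recorded
    max-pooling indices, fused by convolutional skip connections and a
    dilated-convolution head, trained with a differentiable (soft) IoU loss
    and early stopping on validation loss.  Includes CLAHE contrast
    enhancement, deterministic eight-fold rotation/flip augmentation,
    pixel-level Dice/IoU/precision/recall evaluation with normalized
    confusion reporting, and a synthetic mammogram-phantom generator so the
    whole pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
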