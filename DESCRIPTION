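Package: simplifruit
Title: Simplified Anchor-Free Network Topology for Fruit Detection, Tracking and Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, audits, trains and deploys a simplified anchor-free
    convolutional detector for dense fruit targets in orchard imagery. The
    network uses only plain convolutions, max-pooling, feature concatenation
    and an SPPF block in a 32-block backbone/neck, with a decoupled
    regression/classification head; boxes are regressed with a CIoU plus
    distribution-focal loss and classes with binary cross-entropy. The
    package provides declarative topology construction with parameter and
    layer audits, an operator-census graph export, YOLO-format annotation
    I/O with letterbox/mosaic/HSV augmentation, a seeded synthetic orchard
    scene generator, a from-scratch training and inference engine,
    precision/recall/mAP evaluation, and IoU-association tracking for
    counting fruit across video frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    grDevices,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
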