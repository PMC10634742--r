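Package: axseg
Title: Sparse-Label 3D Axon Segmentation for Light-Sheet Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fine-tuning and evaluating 3D convolutional
    segmentation of axonal structures in light-sheet microscopy volumes
    annotated on a sparse subset of z-slices.  Provides a synthetic
    tubular-phantom generator with dense ground truth, edge-class
    derivation around annotated axons, corner-based training-window
    sampling with foreground oversampling, co-registered spatial and
    intensity augmentation, a compact 3D encoder-decoder network with
    layer-selective fine-tuning and a masked class-weighted cross-entropy
    loss, sliding-window inference with Gaussian-weighted overlapping
    window fusion, and edge-tolerant precision/recall/F1 evaluation
    restricted to labeled slices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
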