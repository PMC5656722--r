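Package: octwall
Title: Arterial Wall Layer Segmentation and Healthy-Region Detection in
    Intracoronary Optical Coherence Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully automatic analysis of intravascular optical coherence
    tomography (OCT) cross-sections. Segments the intima-media,
    media-adventitia and adventitia-periadventitia interfaces of the
    arterial wall simultaneously, as three non-crossing closed contours,
    by dynamic programming in a 4D multi-parametric space driven by
    derivative-of-Gaussian edge costs on a lumen-flattened polar
    sub-image. Contour-derived per-A-line features (gray-level
    co-occurrence texture, gradient and geometric descriptors) feed a
    boosted-stump classifier that labels each angular sector of the wall
    as healthy or diseased, with adjacent-frame majority voting and
    circular morphological cleanup. Includes a synthetic phantom
    generator with known ground truth, evaluation metrics (point-to-point
    contour error, layer-thickness agreement, Dice, accuracy, sensitivity,
    specificity), and command-line entry points for segmentation,
    training, classification and evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    ranger,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
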