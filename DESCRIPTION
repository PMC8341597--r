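Package: ivusseg
Title: Synthetic Intravascular Ultrasound Phantoms, U-Net Segmentation and
    Clinical Vessel Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for developing and evaluating semantic segmentation of
    coronary intravascular ultrasound (IVUS) cross-sections. Provides a
    speckle phantom simulator that renders pullback sequences of B-mode
    frames with paired five-class label masks (background, lumen, media plus
    plaque, calcification, stent) and analytic ground truth; a color-coded
    PNG mask codec; a trainable U-Net implemented natively (convolutions and
    backpropagation in C++ via 'RcppArmadillo'); clinical assessment of
    masks (lumen area with the 4 mm^2 narrowed-lumen rule, calcification arc
    and quadrant severity, stent-strut extraction and matching); a
    segmentation evaluation suite (per-class and mean IoU and Dice,
    image-level classification metrics, lumen-area rank correlation); and a
    pipeline orchestrating simulate, split, train, predict, assess and
    evaluate stages with per-stage seeds and manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
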