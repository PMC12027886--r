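Package: cucumgrade
Title: Marker-Calibrated Cucumber Grading with RGB-Encoded Training Canvases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for grading cucumbers from photographs of a
    white board with fiducial corner markers. Detects the markers, derives a
    pixel-to-centimetre calibration so measurements are independent of camera
    distance, segments the cucumber by colour, and measures its calibrated
    height, width and area. Training canvases for a shallow convolutional
    network are built in two flavours: a plain black background with the
    measurements passed as side-channel numerics, and a background whose B, G
    and R channels encode the normalized height, width and area so the network
    receives size metadata as pixels. Includes a synthetic board-and-cucumber
    scene generator with exact ground truth, the shallow CNN in both variants,
    and a replicated multi-metric evaluation protocol (accuracy, macro recall,
    macro precision, macro F-measure) over the seven market grades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
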