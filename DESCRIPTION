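Package: maizetraj
Title: Leaf and Stalk Trajectory Detection in Maize Field Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects maize leaves and stalks in RGB field images and localizes
    their growth trajectories. Implements a two-stage detector (convolutional
    backbone with a feature pyramid, region proposal network, RoIAlign box
    head) extended with a lightweight keypoint branch that predicts all of an
    instance's trajectory points in a single heatmap, together with the
    dotted-line annotation pipeline (coordinate scaling, bounding-box
    synthesis, polyline interpolation and equal-interval keypoint
    subsampling), hard/soft non-maximum suppression with an optional
    distance-IoU overlap, precision/recall/mAP detection metrics, and the
    mean-line-distance (mLD) metric that scores predicted trajectory points by
    their shortest distance to the annotated polyline. A deterministic
    generator of synthetic maize-like field scenes makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    yaml,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
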