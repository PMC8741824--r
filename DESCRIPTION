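Package: spotweed
Title: Colour-Based Fallow Weed Detection, Zoned Actuation and Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects green weeds in images of fallow fields using four
    colour-based segmentation algorithms (excess green, normalised excess
    green, HSV band thresholding, and their conjunction), runs the full
    frame-processing pipeline (resize, defined and adaptive thresholds,
    morphological cleaning, connected-component detection with a minimum
    object size), maps detections to lateral actuation zones driving an
    abstract relay backend, scores detections against ground truth with
    precision and recall, and generates parametric synthetic field scenes
    with exact ground truth for end-to-end testing without field video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: ImageSegmentation, Agriculture
RoxygenNote: 7.3.3
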