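Package: stickytrap
Title: Tiled Detection and Population Monitoring for Sticky-Trap Pest Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detector-agnostic toolkit for counting tiny greenhouse pests on
    yellow sticky-trap boards imaged at high resolution. Provides deterministic
    overlapping-tile cropping so small insects occupy a usable fraction of a
    detector's input, distance-IoU non-maximum suppression (DIoU-NMS) to merge
    duplicate detections across tile overlaps while keeping adjacent insects
    apart, detection evaluation (precision/recall/F1, PR-curve AP and mAP,
    confusion matrix with a background class), mosaic and tile-based training
    set augmentation, network shape and receptive-field arithmetic, a synthetic
    trap-scene generator with exact ground truth, a classical color-blob
    reference detector so the pipeline runs without trained weights, and
    per-day pest-population time-series aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
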