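Package: busroi
Title: Edge-Based Selection and Evaluation of Tumor Bounding Boxes in Breast Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing the region of interest (ROI) that contains a
    tumor in breast ultrasound (BUS) images by scoring candidate bounding boxes
    against an edge map. Implements the SD metric (edge mass S times
    above-threshold edge density D) with adaptive intermode histogram
    binarization, the argmax selection rule over boxes proposed by multiple
    object detectors, baseline box-combining methods (average, union,
    intersection) with failed-model exclusion, pixel-overlap
    precision/recall/F1 evaluation with per-class aggregation, artificial-RGB
    preprocessing of grayscale ultrasound images, and a synthetic phantom
    generator that makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
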