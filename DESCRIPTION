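Package: cxrfuse
Title: Weighted Bounding-Box Fusion and Evaluation for Chest X-Ray
    Detection Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for combining and evaluating bounding-box predictions
    from multiple object detectors of pneumonia-consistent findings in
    chest X-rays, without any GPU or trained network. Implements axis-
    aligned box geometry and intersection-over-union, reading and writing
    detections in the RSNA challenge CSV dialect and COCO-style JSON,
    percentile contrast stretching and bilinear resizing of grayscale
    images, the focal, focal Tversky, categorical cross-entropy and
    smooth-L1 loss functions, confidence filtering, greedy non-maximum
    suppression, rank-weighted averaging ensembles of overlapping boxes,
    precision-recall / average-precision evaluation with greedy IoU
    matching, binomial confidence intervals (Clopper-Pearson and normal
    approximation), and a seeded generator of synthetic multi-detector
    scenarios for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
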