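Package: refinebank
Title: Refinement Filter Bank for Plant-Disease Object Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage refinement of bounding-box detections for plant
    disease and pest diagnosis. A primary detector (real or simulated)
    proposes boxes; a bank of per-class binary verifier networks judges
    each box and an integration stage keeps true positives while
    discarding false positives. Includes Pascal-VOC-style evaluation
    (IoU matching, 11-point interpolated average precision, IoU-threshold
    sweeps, TP/FP summaries), a calibrated detector simulator, a
    synthetic greenhouse-scene generator with class-unbalanced and
    confusable disease appearances, Pascal VOC XML and detection CSV/JSON
    input and output, and an end-to-end reproduction pipeline.
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
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
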