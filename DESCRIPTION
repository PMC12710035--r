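Package: podkit
Title: Prototype-Mask Instance Segmentation Toolkit for Field Pod Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and auditing lightweight prototype-mask
    instance-segmentation networks for side-view plant (soybean pod) imagery,
    together with the surrounding pipeline: symbolic model graphs with exact
    fused parameter and FLOP accounting for a YOLOv8n-seg-style baseline and
    its hierarchical prototype aggregation (HPA) and U-shaped EMA-attention
    decoder variants; prototype-coefficient mask assembly and mask-mAP
    evaluation (IoU, precision/recall, mAP@50, mAP@50-95); no-reference
    image-quality screening of video frames (clarity, edge sharpness, entropy,
    co-occurrence energy) with two-stage thresholding; polygon label I/O,
    dataset splitting, statistics and augmentation; and a synthetic backdrop
    scene generator so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
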