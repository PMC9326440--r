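Package: soyphen
Title: Soybean Flower and Pod Phenotyping: Detection Evaluation, Anchor
    Optimization, Counting Agreement and Drop-Rate Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for image-based soybean flower and pod
    phenotyping studies. Reads and writes PASCAL VOC bounding-box
    annotations, rescales them to a working resolution and performs
    deterministic train/validation/test splitting; optimizes detector
    anchor boxes by k-means under the 1-IOU distance with mean-IOU elbow
    analysis, aspect-ratio derivation and COCO-style size stratification;
    scores detections against ground truth (precision, recall, average
    precision, mAP and segmentation mean-IoU); runs a serial
    flower-then-pod fusion counting pipeline over per-node images and
    quantifies agreement with manual counts; and computes flower/pod fate
    statistics across soybean reproductive stages R1-R8, including drop
    rates, stage breakdowns, node-layer distributions and daily standing
    counts. A seeded synthetic-data module generates annotation sets,
    noisy detections with known error rates, and stochastic flower-fate
    event logs, so every stage is testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
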