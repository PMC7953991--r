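Package: tasseltrack
Title: Spatiotemporal Anthesis Extraction from Time-Lapse Maize Tassel Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated sequential pipeline for extracting flowering (anthesis)
    patterns of field-grown maize tassels from time-lapse RGB imagery: bounding-box
    detection with quality control and IOU/mAP evaluation, a small convolutional
    tassel/non-tassel classifier, k-means temporal tracking of tassel identities,
    classical and trainable encoder-decoder segmentation with pixel accuracy and
    mIOU, skeleton-graph morphometry of the main spike (longest path, branch
    points, per-pixel width), and tip-anchored width-over-time surfaces from which
    flowering onset position, spread direction and duration are quantified. Includes
    a procedural time-lapse scene generator with full ground truth so every stage
    is testable without field data or trained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
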