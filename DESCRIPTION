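Package: cellmotr
Title: Detection, Tracking and Integrative Motility Analysis of Cells in
    Multi-Channel Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking motile cells (T lymphocytes in particular) in
    co-registered multi-channel 2D time-lapse microscopy. Cells are detected
    in transmitted-light frames by Canny edge extraction followed by a
    gradient-directed circular Hough transform, tracked by conservative
    nearest-neighbour association into confident segments that are then
    joined end-to-end by a similarity-scored Hungarian assignment, and
    characterised by local segmentation of reflection and fluorescence
    channels (contact area, attachment, mean dye intensity, aspect ratio).
    Per-track motility statistics (speed, turn angle, arrest coefficient,
    confinement index) are computed with proper handling of frame gaps. A
    companion evaluation suite scores detection and tracking against
    bounding-box ground truth with Jaccard-based SFDA and ATA metrics, and a
    synthetic movie generator with exhaustive ground truth makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    clue,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
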