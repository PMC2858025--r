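Package: celltracker
Title: Automated Cell Identification and Tracking for Time-Lapse Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully automated identification and tracking of unstained cells in
    time-lapse microscopy image sequences. Cell centroids are extracted per
    frame by combining local-entropy cell-region segmentation with local
    intensity thresholding, propagated temporally and consolidated by merging.
    Centroids are linked into tracks by a discrete Kalman filter with a
    constant-velocity motion model and iterative unique-nearest-neighbor data
    association, run backwards in time so that cell divisions appear as track
    merges and new tracks can only start at the image border. Migration rates
    are summarized as per-track mean displacement (MD) and population average
    mean displacement (AMD). The package also quantifies the error sources of
    manual point-and-click tracking (centroid click jitter, representative
    subset selection) via noise-injection and resampling studies, and ships a
    synthetic scene generator with known ground truth for end-to-end
    evaluation of detection and tracking quality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Segmentation, TimeCourse
RoxygenNote: 7.3.3
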