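Package: promptSeg
Title: Promptable Interactive and Automatic Instance Segmentation for Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interactive, prompt-driven instance segmentation for microscopy
    images, decoupled from any specific network through a promptable-model
    contract. Implements iterative prompt-simulation training with interleaved
    distance-decoder training, automatic instance segmentation (AIS) via
    foreground/center-distance/boundary-distance channels decoded with a seeded
    watershed, automatic mask generation (AMG) from point grids with predicted
    IoU and stability filtering plus non-maximum suppression, the simulated
    interactive-annotation evaluation protocol with the mean segmentation
    accuracy (mSA) metric, threshold calibration by grid search, and
    projection/merging logic for volumetric segmentation and tracking. A
    deterministic synthetic generator of microscopy-like images and labels
    makes every algorithm testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
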