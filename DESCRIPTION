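Package: acidrop
Title: Single-Cell Extracellular Acidification Analysis for Droplet Microwell Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end image analysis for ratiometric extracellular pH
    monitoring of single cells encapsulated in picoliter droplets immobilized
    in a microwell array. Provides a ground-truthed synthetic scene generator
    (Poisson cell encapsulation, two labelled cell populations, dual-emission
    ratiometric pH probe rendering, photobleaching), feature-point cell
    detection and Brownian track linking, droplet segmentation and grid
    indexing with central-area occupancy assignment and cross-channel
    reconciliation, conversion of dual-emission probe intensities into pH
    trajectories and raw pH drops, and quality control with encapsulation and
    error-rate accounting plus group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    clue,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
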