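Package: synquant
Title: Interaction Scoring and Image Quantification for Synaptogenesis Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for split-DHFR protein-complementation
    interaction screens and fluorescence assays of presynaptic
    differentiation. Computes normalized interaction scores from microplate
    OD600 growth kinetics (blanking, log2 transform, windowed slope fitting,
    MTX/DMSO ratios, control-anchored scoring, specificity calls, binned
    heatmaps), and recruitment/co-clustering measures from multi-channel
    fluorescence images (threshold ROIs, Euclidean-disk dilation, mask
    algebra, rolling-ball background subtraction, contact-area measures,
    surface-expression matching, per-culture normalization). Includes
    synthetic plate and microscopy-scene generators with known ground truth
    for validation, and rank-based group statistics with Dunn's post hoc
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
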