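Package: vesselmetrics
Title: Morphometry of Retinal Vascular Networks from Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative morphometry of the developing retinal vasculature
    from binarized fluorescence flatmount images and confocal z-stacks.
    Implements the classic flatmount processing chain (8-bit conversion,
    adaptive local-mean thresholding, despeckling, region-of-interest
    masking), topology-preserving skeletonization with a classified
    skeleton graph (segments, junction clusters, endpoints), and six
    vascular parameters: area fraction, length density, branch-point
    density, nearest-neighbour distance (mean and variability), and radial
    outgrowth. Supports both collapsed whole-retina analysis of maximum
    projections and per-plexus analysis of high z-resolution stacks, with
    the sum/average aggregation rule and percent-deviation arithmetic used
    to compare the two modes. Includes a synthetic vascular-network
    generator with exact geometric ground truth for validating every
    stage, tiled area-fraction heatmaps, and tidy tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
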