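Package: gelcaller
Title: Automated Lane Segmentation, Band Extraction and Genotype Calling
    for 1-D Gel Electrophoresis Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyses 8-bit grayscale densitometry images of one-dimensional
    gel electrophoresis (PAGE or agarose). Lanes are segmented even when
    curved, by splitting the image into dynamic-height horizontal strips,
    locating lane boundaries in smoothed cumulative column-intensity
    histograms per strip, and stitching boundaries across strips with a
    shortest-path assignment. Distorted (smiling, frowning or slanted)
    bands are straightened by per-column cross-correlation against a
    reference column, and bands are called from the summed lane profile by
    first-derivative peak finding with a percentile background threshold.
    Band mobilities relative to a reference band are clustered across lanes
    with density-based clustering (DBSCAN) and per-cluster Gaussians give
    maximum-likelihood genotype calls. A synthetic gel-image generator with
    full ground truth (curved lanes, smiling bands, doublets, background
    gradients, speckle and noise) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
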