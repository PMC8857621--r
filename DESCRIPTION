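Package: choroseg
Title: Binarization and Vascularity Analysis of the Choroid in OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify choroidal vascularity in optical coherence
    tomography (OCT) B-scans. Implements A-scan flattening of the curved
    inner choroidal boundary, Niblack local thresholding with a window-size
    sweep to separate vessel lumen from interstitial stroma, construction of
    three-category ground-truth label maps with a painted scleral mask,
    tiling and subject-grouped splitting for semantic-segmentation training,
    a compact U-Net / SegNet-style encoder-decoder trained with Adam and
    cross-entropy, and a full evaluation suite covering per-class accuracy,
    intersection over union, choroidal vascularity index (CVI), repeatability,
    intraclass correlation and Bland-Altman limits of agreement. A synthetic
    speckle-phantom generator with known vessel geometry makes the whole
    pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    tidyr,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    png,
    tiff,
    withr,
    rlang,
    generics,
    stats,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
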