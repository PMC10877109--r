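Package: histoclust
Title: Weakly Supervised Clustering of Primary Liver Cancer Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying primary liver cancers from routine-stained
    biopsy whole-slide images without exhaustive tumour-type labels. The
    pipeline tiles annotated slides into fixed-size patches with background
    masking, trains a small convolutional tumour/non-tumour classifier under
    weak supervision, pools its last convolutional layer into per-patch
    features, halves their dimension with principal component analysis,
    clusters tumour tiles with a Gaussian mixture model fitted by
    expectation-maximization, and aggregates tile clusters into per-slide
    contingent proportions, major-contingent diagnoses, and agreement and
    correlation summaries against pathology and quantitative
    immunohistochemistry. A seeded phantom-biopsy simulator with exact ground
    truth makes the full pipeline testable without any real slide.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    png,
    stats,
    grDevices,
    tools,
    generics,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
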