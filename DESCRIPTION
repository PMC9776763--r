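Package: erallred
Title: Automated Allred Scoring of ER-IHC Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automated estrogen-receptor (ER) status evaluation for
    immunohistochemistry-stained breast-carcinoma images.  Nuclei are
    detected by regressing a distance-transform score map with a compact
    convolutional network, split by seeded watershed, and filtered by
    area; each cell is classified as negatively or positively stained
    from centroid-weighted hue and value, and positive cells are graded
    weak, moderate or strong by a small convolutional classifier.
    Per-slide class proportions are converted into Allred proportion,
    intensity and total scores with a hormonal-therapy recommendation.
    Includes a synthetic stained-field generator with exact ground truth,
    an evaluation harness (detection matching, confusion metrics,
    slide-level agreement statistics), and a bundled 40-slide reference
    evaluation cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
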