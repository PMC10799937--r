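Package: snagmap
Title: Individual Dead Tree Mapping from Sub-Metre Four-Band Aerial Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and characterises individual standing dead trees (snags) in
    4-band (RGB + near-infrared) sub-metre aerial imagery. A compact
    encoder-decoder network predicts ordinal distance-to-boundary energy levels
    and a marker-based watershed separates touching crowns into instances.
    Downstream tools compute crown geometry (filled area, centroid,
    eccentricity), classify brown- versus grey-stage mortality from mean crown
    colour in HSV space, aggregate counts and canopy metrics onto regular grids
    with mean-error bias correction, attribute damage agents by year-precedence
    polygon overlay, and evaluate counts and masks (MAE, relative total error,
    count bias, IoU) against labels and field observations. A synthetic scene
    generator with exhaustive ground truth makes the full pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    jsonlite,
    tiff,
    EBImage,
    ggplot2,
    Rcpp,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
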