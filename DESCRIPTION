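Package: morphosignal
Title: Local Mapping of Binary Signals on 3D Landmark Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Geometric-morphometric toolkit for locating where on a 3D
    landmark/semilandmark configuration a binary biological signal (such as
    sex) is expressed. Implements generalized and ordinary Procrustes
    analysis, symmetrization, thin-plate-spline warping and per-vertex
    area-change maps; shape-space and form-space principal component
    analysis; cross-validated linear discriminant accuracy with stratified
    train/test splits; Procrustes linear models with permutation tests;
    digitization-error repeatability via Procrustes ANOVA; allometric
    trajectory comparison with a permutation test on the between-group
    angle; and the core per-point neighborhood accuracy-mapping pipeline
    that runs an independent local Procrustes fit, principal component
    reduction and discriminant analysis around every landmark. Includes a
    synthetic landmark generator with planted localized effects, size
    dimorphism and allometry for validation, plus readers and writers for
    CSV, TPS and 3D Slicer fcsv landmark files and colored ASCII PLY
    meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    optparse,
    igraph,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
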