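Package: maizeskel
Title: Curve-Skeleton Extraction and Phenotypic Trait Estimation from 3D
    Point Clouds of Maize Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts curve skeletons from colored terrestrial-laser-scan
    point clouds of single maize plants and estimates organ-level phenotypic
    traits from them. The pipeline removes pot points by an
    illumination-robust color difference, filters scanning noise by radius
    clustering, contracts the cloud onto its skeleton with an iterative
    constrained cotangent-Laplacian solve, reduces the contracted points to
    skeleton key points by directionality-adaptive sphere sampling, connects
    them into a tree (3-nearest-neighbor graph with coplanarity/growth
    weighted loop breaking), segments stem and leaves, calibrates the
    skeleton against the original cloud by cutting-plane resampling, and
    derives leaf length, inclination angle, top length, azimuth angle,
    growth height and plant height. A procedural maize-plant generator with
    exact ground-truth skeletons supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
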