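Package: ratlas
Title: Cross-Atlas Alignment and Data Migration for Rat Brain Reference Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aligning rat-brain stereotaxic reference spaces. Provides
    a craniometric registry of Paxinos-Watson and Swanson atlas levels indexed
    by anteroposterior distance from Bregma, classification of cross-atlas level
    pairs as fully, narrowly, or not in register, a feature-based plate matcher
    (difference-of-Gaussians keypoints with 128-dimensional gradient-orientation
    descriptors, ratio-test matching, and RANSAC homography ranking), migration
    of point-source experimental data between atlas coordinate frames by
    anisotropic scaling, and quantitative vector analysis of expert-guided
    corrections. Includes generators for synthetic histology-like test imagery
    and point datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
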