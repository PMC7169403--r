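Package: lvmark
Title: Left-Ventricle Border Marking with a Gabor-Guided Anisotropic
    Generalized Hough Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic delineation of the left-ventricular endocardial
    border on 2-D echocardiography-like grayscale images.  A Gabor filter
    bank localizes the region of interest, an anisotropic generalized
    Hough transform (R-table voting over position, two orthogonal scales
    and rotation) localizes a guided deformable template whose thin septal
    limb anchors the pose and whose thick lateral band is deformed to the
    image gradient by dynamic programming.  Candidate poses are ranked by
    accumulator rate and a support-vector-machine confidence score is
    computed from accumulator-space summary features.  A seeded synthetic
    phantom generator with known ground-truth boundaries supports testing
    and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
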