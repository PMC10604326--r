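Package: humerusSSM
Title: Statistical Shape Modelling and Measurement-Based Prediction of the
    Proximal Humerus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building point-distribution statistical shape models
    (SSMs) of the humerus from corresponded triangle surface meshes and for
    predicting the proximal humeral segment from a small set of geometric
    measurements (maximum length, head radius, shaft circumference).
    Includes triangle-mesh input/output (STL, PLY, OBJ) and geometric
    primitives (plane cuts, mirroring, sphere and cylinder-axis fitting), a
    parametric synthetic-humerus generator with known dense correspondence
    for validation, rigid iterative-closest-point and generalized Procrustes
    alignment without scaling, Laplacian-regularized non-rigid template
    warping for dense correspondence, PCA shape models with compactness
    diagnostics, measurement-augmented models with Gaussian conditional
    prediction, anatomical measurement operators in a humeral coordinate
    system, intraclass correlation for measurement reliability, and
    surface-deviation part comparison against the contralateral-mirroring
    baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
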