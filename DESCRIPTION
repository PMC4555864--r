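Package: alphamass
Title: Volumetric Body-Mass Estimation from Skeletal Point Clouds via Alpha-Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits families of size-normalized alpha-shapes to three-dimensional
    point clouds of articulated skeletons and estimates body mass from the
    enclosed volume. An alpha-complex engine (Delaunay tetrahedralization with
    circumradius filtering and prefix-sum volume queries) computes shape volumes
    across a sweep of refinement coefficients; log-log ordinary least-squares
    calibration against a reference sample of known masses selects the optimal
    refinement, and the fitted allometric model predicts the mass of new
    (e.g. fossil) skeletons. Includes point-cloud readers and writers (XYZ, PLY,
    OBJ), reproducible seeded downsampling, a synthetic skeleton generator with
    analytically known volumes for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
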