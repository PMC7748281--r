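Package: focal3d
Title: Grid-Based Density Clustering for 3D Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast, deterministic density-based clustering of 3D single-molecule
    localization microscopy (SMLM) point clouds on a voxel grid (the FOCAL3D
    algorithm), together with an objective parameter-selection procedure that
    calibrates the density threshold against a complete-spatial-randomness
    surrogate and locates plateaus of parametric insensitivity. Includes a
    synthetic SMLM cluster generator with a fluorophore blinking model and
    ground-truth labels, and validation metrics: precision/recall/F1 against
    ground truth, a cluster-level silhouette score, convex-hull effective
    cluster radii, and 3D Ripley's K/H point-pattern analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    data.table,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
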