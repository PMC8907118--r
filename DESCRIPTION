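Package: cortrec
Title: Cortical Surface Reconstruction from Volumetric Level-Set
    Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstruction of cortical surfaces from T1-weighted-like MR
    volumes through an implicit signed-distance (level-set) representation.
    Provides synthetic brain phantoms with exactly known inner ("white") and
    outer ("pial") surfaces; exact mesh-to-level-set encoding; volumetric
    topology correction by homotopic growth with simple-point tests on the
    Freudenthal complex; topology-preserving isosurface extraction; a
    configurable 3D U-Net (softmax segmentation and level-set regression
    heads) with patch training and sliding-window inference; surface
    morphometrics (cortical thickness, sulcal depth), mesh quality,
    surface displacement, parcellation Dice and test-retest instability;
    and readers/writers for NIfTI volumes, FreeSurfer binary surfaces and
    overlays, OFF/PLY meshes and per-vertex label maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
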