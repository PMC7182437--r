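Package: kneessm
Title: Tibio-Femoral Statistical Shape Modelling and Knee Instability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a joint statistical shape model (SSM) of the distal femur
    and proximal tibia from corresponding surface points and relates its modes
    of variation to clinical knee-alignment angles. Provides a parametric
    synthetic knee-cohort generator with known ground-truth deformities,
    triangle-mesh processing (smoothing, decimation, isotropic remeshing,
    Hausdorff distances, PLY/STL/OBJ input and output), rigid and coherent
    point drift registration with reference-indexed dense correspondences,
    PCA shape-space construction with explained variance, morphing and
    projection, computation of the five clinical alignment angles
    (hip-knee-ankle, femoral and tibial varus-valgus, internal-external
    rotation, tibial slope) with stability labelling, and discriminant /
    logistic-regression classification of instability with leave-one-out
    validation, rank tests and Spearman correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
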