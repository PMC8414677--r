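Package: MCmorph
Title: Morphometry of the Meckel Cave from Binary Segmentation Masks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-dimensional shape radiomics for bilateral Meckel-cave
    segmentations. Reads binary masks in NIfTI-1 format, extracts ten
    shape features (voxel volume, triangulated surface area, maximum 3D
    and per-plane 2D Feret diameters, principal-component axis lengths
    and flatness) via a watertight isosurface mesh, and runs the full
    group/side/neurovascular-contact stratified statistical comparison
    pipeline for trigeminal-neuralgia cohorts (binomial laterality test,
    paired and regression-based feature comparisons, Kendall tau-b
    correlation screen, demographic and cross-tabulation tables). A
    synthetic bilateral-cohort generator produces ellipsoidal phantoms
    with known ground-truth flatness and volume so every stage can be
    validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
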