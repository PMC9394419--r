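Package: trusfit
Title: Semiautomatic Prostate Segmentation from TRUS by Deformable
    Superellipses, with Mask-Based MRI-TRUS Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits deformable superellipses (translation, rotation, linear
    tapering and circular bending of a superellipse) to sparse user-annotated
    boundary points on axial transrectal-ultrasound slices, reconstructs the
    3D prostate gland by linear interpolation of the per-slice parameter
    vectors, and registers MRI and TRUS segmentation masks through signed
    Euclidean distance maps with a gradient-descent affine optimizer.
    Includes closed B-spline contour fitting for refined mid-gland slices,
    the standard volumetric and surface evaluation metrics (Dice, Jaccard,
    VOE, RVD, Hausdorff, ASSD), a synthetic phantom and annotator generator
    so the whole pipeline is testable without patient data, readers and
    writers for NIfTI and NRRD volumes and 3D Slicer markups JSON, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    mgcv,
    jsonlite,
    EBImage,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
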