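Package: canopyscan
Title: Low-Cost Multi-View 3D Plant Phenotyping and Growth Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turntable-based multi-view 3D reconstruction of single plants and
    whole-growth-period phenotype analysis. Provides a pinhole camera model with
    radial distortion and RANSAC-robust planar calibration, wavelet denoising and
    blue-screen segmentation of turntable images, triangulation of multi-view
    correspondences into coloured point clouds, Poisson surface reconstruction
    (octree, B-spline basis, Gauss-Seidel solver, marching tetrahedra), extraction
    of six canopy traits (plant length, width, height, canopy height, canopy area,
    plant volume), and logistic growth-curve fitting with growth-rate curves,
    maximum-rate timing and normalized phenotypic-fingerprint matrices. Includes a
    synthetic-fixture generator (parametric plants, rendered calibrated views,
    noisy logistic trait series) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    png,
    EBImage,
    minpack.lm,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
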