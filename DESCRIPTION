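Package: overlapdose
Title: Overlap-Based Prediction of Organ-at-Risk Dose-Volume Metrics in
    Prostate Radiotherapy Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Voxel-based tools for studying how well overlap-derived
    geometric parameters predict organ-at-risk dose in conformal prostate
    radiotherapy.  Provides rasterization of analytic structure sets onto
    dose grids, anisotropic margin expansion by Euclidean distance
    transforms, generators for systematically varied prostate, rectum and
    bladder phantom geometries, a seeded sigmoid-falloff emulator of
    conformal planned dose with IMRT- and VMAT-like presets, dose-volume
    histogram metrics (V_xGy, D_p, mean dose, conformity number,
    homogeneity index), the conventional and volume-ratio-weighted overlap
    predictive parameters (COPP and POPP), and a statistical layer that
    sweeps Pearson correlations over 1-Gy dose levels, compares dependent
    correlations, and locates the threshold dose at which the two
    predictors are equally informative.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
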