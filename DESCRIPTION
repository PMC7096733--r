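Package: rehodc
Title: Resting-State ReHo and Degree-Centrality Change Analysis with PAIR SVM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for within-subject resting-state
    fMRI stimulation studies. Generates synthetic 4D BOLD cohorts with known
    ground truth, performs minimal time-series cleaning (volume discard,
    Friston-24 motion regression, detrending, band-pass filtering), computes
    voxel-level regional homogeneity (Kendall's coefficient of concordance)
    and weighted positive degree-centrality maps, runs voxelwise
    repeated-measures ANOVA with Gaussian-random-field cluster correction and
    pairwise paired t tests, and discriminates stimulation conditions with a
    PAIR support vector machine under repeated split-half cross-validation,
    including weight back-projection and single-voxel ROC/AUC.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite
Config/testthat/edition: 3
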