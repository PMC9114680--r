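Package: mpMRIseg
Title: Semi-Automatic Tumor Segmentation from Multiparametric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelwise machine-learning segmentation of rectal tumors from
    multi-sequence magnetic resonance imaging (anatomical T2-weighted,
    multi-echo T2*-weighted, multi-b-value diffusion-weighted and dynamic
    multi-echo contrast-enhanced series). Provides a synthetic multi-sequence
    phantom generator with simulated observer delineations, dynamic time-point
    selection, rigid mutual-information registration and resampling to an
    isotropic grid, per-voxel feature construction with per-patient z-score
    normalisation and random undersampling, four voxel classifiers (LDA, QDA,
    SVM, AdaBoost) under patient-level leave-one-out cross-validation,
    watershed-based semi-automatic post-processing with seeded region
    selection, Dice and mean symmetric surface distance evaluation, and the
    orchestration and statistics (Friedman, Wilcoxon signed rank, Bonferroni)
    for algorithm and feature-set comparison experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    EBImage,
    RNifti,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
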