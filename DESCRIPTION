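Package: lgeseg
Title: Constrained Multi-Class Left-Ventricle Pathology Segmentation from LGE-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for segmenting the left-ventricle cavity,
    myocardium, myocardial-infarction scar and microvascular obstruction (MVO)
    from short-axis late-gadolinium-enhancement MR volumes. It couples an
    anatomical U-Net pre-segmentation with a pathological 3D U-Net trained
    under a variational-autoencoder shape-inclusion constraint and an auxiliary
    patient-level classification constraint, fuses an ensemble of constraint
    weights by per-voxel majority voting, and post-processes with slice-wise
    morphological opening and 3D connected-component filtering. Includes the
    evaluation suite used for challenge-style scoring (Dice, Hausdorff,
    absolute volume difference and its rate, MVO presence accuracy,
    patient classification metrics, Bland-Altman summaries) and a synthetic
    short-axis phantom generator so every stage can be trained and evaluated
    without external data. Networks run on a compact CPU convolution engine
    implemented with Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
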