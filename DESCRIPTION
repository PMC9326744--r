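Package: abdoseg
Title: Multi-Organ Abdominal MRI Segmentation and Volumetry for Polycystic Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Semi-automated segmentation and volumetry of the right kidney,
    left kidney, liver and spleen on axial T2-weighted abdominal MRI, aimed at
    autosomal dominant polycystic kidney disease (ADPKD) monitoring. Provides
    per-organ binary 2D encoder-decoder segmentation networks trained with a
    combined soft-Dice and cross-entropy loss, priority-based adjudication of
    voxels claimed by more than one organ model, midline splitting of the
    merged kidney class into right and left, organ volume and height-adjusted
    total kidney volume (ht-TKV) computation, and an agreement-statistics
    suite (Dice similarity, Lin's concordance, RMSE, percent error,
    Bland-Altman limits, interobserver SD and ICC). A synthetic abdominal
    phantom generator supplies ground-truth labelled volumes so the entire
    pipeline is trainable and testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
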