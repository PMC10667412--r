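Package: focusedcta
Title: Focused-View CT Angiography by Patch-Based 3D Segmentation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Produces "focused view" CT angiography: a two-class volumetric
    segmentation pipeline that extracts the brain (with intracranial
    arteries) and the extracranial stroke-related arteries from CT
    angiography volumes and blanks all remaining anatomy to air (-1000 HU).
    Implements a patch-based 3D U-Net (basic and dual-attention variants)
    trained with the categorical Dice loss under cross-validation with
    early stopping, sliding-window inference with overlap averaging, an
    averaging ensemble, random hyperparameter search over the training
    configuration space, NIfTI and DICOM-series input/output, a synthetic
    head-and-neck CTA phantom generator with ground-truth labels, and the
    statistical toolkit used to evaluate reader studies of the output
    (Dice coefficients, Wilcoxon signed-rank, Mann-Whitney, Yates-corrected
    chi-square, Cohen's weighted kappa, ordinal score summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
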