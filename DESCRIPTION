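Package: dtimt
Title: Diffusion-Tensor Biomarkers for Malignant Transformation of Resected Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for diffusion-tensor-derived
    biomarkers of malignant transformation in resected WHO grade II glioma.
    Generates ground-truth tensor phantoms (resection cavity, T2w-hyperintense
    zone, focal lesion), simulates diffusion-weighted acquisitions with Rician
    noise, fits voxel-wise tensors by log-linear least squares, derives axial,
    mean and radial diffusivity maps from the sorted eigenvalues, extracts
    ROI-minimum biomarkers with two-reader emulation, and runs the statistics
    layer: two-reader contrast-to-noise ratio, signal-drop ratios, ROC
    analysis with a less-than-or-equal positivity rule, Youden cutoffs,
    positive predictive value, weighted Cohen's kappa, and one-way ANOVA with
    Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
Config/testthat/edition: 3
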