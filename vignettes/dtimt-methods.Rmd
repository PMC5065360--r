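---
title: "Diffusion-tensor biomarkers of glioma transformation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-tensor biomarkers of glioma transformation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtimt)
```

## The problem

A WHO grade II glioma that has been resected will, in most patients,
eventually transform into an anaplastic (grade III/IV) tumor. Clinically the
transformation is declared when new contrast enhancement appears on
T1-weighted MRI, but enhancement reflects blood–brain-barrier breakdown,
which *follows* the rise in cellularity. Restricted water diffusion — low
apparent diffusivity — tracks cellularity directly, so diffusion-tensor
imaging (DTI) of the T2w-hyperintense zone around the resection cavity can
carry an earlier signal. The quantity of interest is a per-patient scalar:
the minimum of a diffusivity map inside the tumor ROI (`AD_min`, `MD_min`,
`RD_min`), i.e. the most diffusion-restricted voxel.

This package implements the full quantitative chain — simulation, tensor
estimation, ROI biomarkers, and the statistics layer — so that every stage
is testable without patient data.

## Signal model and simulation

Each voxel carries a symmetric positive-semidefinite tensor $D$ (mm²/s).
A measurement with b-value $b$ and unit gradient $g$ sees

$$S = S_0 \exp(-b\, g^\top D g),$$

and the magnitude image adds Rician noise:
$M = \sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with independent
zero-mean Gaussians of standard deviation $\sigma = \max(S_0)/\mathrm{snr}$.
Rician noise is the standard model for magnitude MRI; its second moment
$E(M^2) = S^2 + 2\sigma^2$ is used as a closed-form check in the tests.

The default acquisition is one $b=0$ measurement plus 12 directions at
$b = 1000$ s/mm², the routine clinical protocol for this application. The
12 directions are not standardised across vendors, so the package ships a
fixed electrostatic-repulsion set as a text fixture
(`inst/extdata/directions12.txt`); reproducibility was preferred over
emulating any particular scanner.

### The phantom

`default_phantom_spec()` describes a 48×48×24 grid at 1.8×1.8×4 mm (the
DTI resolution of the emulated protocol): anisotropic background white
matter with eigenvalues (1.7, 0.4, 0.3)·10⁻³ mm²/s (a literature-typical
default, not a study estimate), a CSF-filled resection cavity (isotropic
3.0·10⁻³), a T2w-hyperintense zone at the stable-cohort axial level
(isotropic 1.28·10⁻³), and a focal lesion inside it at the
transformed-cohort level (isotropic 0.72·10⁻³). S0 levels (800/1000/900/850
arbitrary units) order the tissues as a b0 EPI image would: CSF brightest,
edema brighter than normal white matter. Region geometry is painted in
order; a lesion outside the hyperintense zone is rejected as a geometry
error, because the biomarker is defined on the hyperintensity.

The phantom reproduces the *contrast structure* of the clinical problem,
not its anatomy: regions are homogeneous, boundaries are geometric, there
is no CSF partial-voluming, no eddy-current or susceptibility distortion,
and no surgical blood products. Passing tests therefore demonstrate
correctness of the estimators and statistics under the stated noise model,
not robustness to all real-world artifacts. An exclusion-mask input on the
ROI readout stands in for the manual artifact check radiologists perform
before trusting a minimum value.

### The cohort generator

`simulate_cohort()` draws per-subject biomarkers from group-wise normal
distributions, truncated at zero by redrawing (diffusivities are
physical). Defaults are 29 stable vs 18 transformed subjects with
means ± SD (10⁻³ mm²/s): axial 1.28 ± 0.31 vs 0.72 ± 0.23, mean
1.00 ± 0.26 vs 0.64 ± 0.21, radial 0.97 ± 0.26 vs 0.56 ± 0.20. The three
parameters are drawn *independently* per subject; real AD/MD/RD minima are
strongly correlated, so cross-parameter joint statistics (e.g. the
correlation of AUCs across parameters) should not be read off this
generator. Under the ≤-positivity rule its large-sample AUC has the
binormal closed form
$\Phi\!\left(\Delta\mu/\sqrt{\sigma_1^2+\sigma_2^2}\right)$
(`binormal_auc()`), which serves as the analytic reference — for the
default axial parameters ≈ 0.927. Truncation at zero shifts the
transformed-group mean by less than 0.001·10⁻³ mm²/s, visible as a ≈0.003
upward shift of the empirical AUC, well inside the tolerance used in the
tests.

## Tensor estimation

`fit_tensor()` solves, per voxel, the log-linearised model
$\ln S_i = \ln S_0 - b_i\, g_i^\top D g_i$ by ordinary least squares for
seven unknowns (six tensor components, $\ln S_0$). Ordinary rather than
weighted least squares is the default because it is deterministic, exact
in the noiseless limit, and — measured on the default phantom at snr 20 —
its regional MD readout is essentially unbiased (median signed error
≈ −0.2%). A signal-weighted variant (`weighted = TRUE`, weights ∝ squared
observed signal) is available; at these acquisition settings it does not
improve the readout, because the error is dominated by per-voxel dispersion
rather than bias. With 13 measurements at snr 20 the per-voxel MD error has
a median magnitude of ≈4%; the tests therefore assert a 2% bound on the
*regional* (median-over-ROI) accuracy — the quantity the ROI analysis
consumes — and regression-bound the per-voxel dispersion at its observed
level rather than claiming a per-voxel accuracy the acquisition cannot
deliver.

Voxels with any non-positive signal are flagged invalid (`NaN` in all
maps) instead of being fitted; a gradient design of rank < 7 rejects the
whole volume, naming the deficient rank. Multiple $b=0$ measurements enter
the regression as separate rows rather than being pre-averaged, which keeps
the least-squares problem unbiased.

`eigendecompose()` sorts eigenvalues descending and clamps anything below
$10^{-12}$ mm²/s to that floor, counting clamped voxels (`n_clamped`) so
noise problems surface in logs instead of being silently hidden. The maps
follow directly: AD = λ₁, RD = (λ₂+λ₃)/2, MD = (λ₁+λ₂+λ₃)/3, which forces
AD ≥ MD ≥ RD and the identity MD = (AD + 2·RD)/3 voxel-wise.

A consequence worth knowing: in *isotropic* tissue, sorting noisy
eigenvalues biases λ₁ upward and λ₃ downward, so AD is hyperintense and RD
hypointense relative to MD in noise — this, not microstructure, is why the
axial map shows the strongest tumor-to-edema contrast in the simulated
pipeline, echoing the white-matter-hyperintensity argument for AD's higher
CNR in clinical data.

## ROI metrics

`extract_roi_stats()` reports mean, sample SD (n−1 denominator, matching
common radiology tooling), minimum, and the minimum's voxel coordinates,
after excluding invalid voxels and an optional artifact-exclusion mask.
Ties for the minimum break toward the smallest linear index in x-fastest
order, so readouts are platform-deterministic.

The two-reader CNR divides the difference of reader-averaged ROI means
(T2w-hyperintense minus tumor) by the *sum* of the two reader-averaged ROI
standard deviations. The plain-sum denominator is the formula as printed in
the source methodology; it is unusual (a pooled SD would be smaller) but is
retained verbatim since CNR is only compared across maps, where any common
factor cancels. Degenerate constant ROIs with unequal means raise an
explicit division-by-zero error; equal means return CNR = 0.

Because the real study's readers drew ROIs independently,
synthetic runs emulate a second reader by toggling boundary voxels of the
first reader's mask with probability 0.3 under a fixed seed
(`perturb_mask()`): interior voxels never change, so the perturbation
mimics contouring disagreement rather than gross mislabeling.

For the agreement statistic on cohorts, each reader's binary rating
("diffusion restriction present") is emulated by adding independent
Gaussian reader noise (default SD 0.05·10⁻³ mm²/s, a few percent of the
biomarker scale) and thresholding at the parameter's Youden cutoff. The
rated unit is the subject; with 47 subjects and strong group separation
this lands the kappas in the 0.7–0.9 range.

## Statistics layer

* **ROC** — thresholds at midpoints between consecutive sorted unique
  values plus ±∞; the trapezoidal AUC provably equals the Mann–Whitney
  concordance with ½ credit for ties (property-tested against a
  brute-force pairwise oracle). The operating cutoff maximises Youden's J,
  ties toward the smaller cutoff; the AUC standard error is Hanley–McNeil.
* **PPV** — `100·TP/(TP+FP)` at the operating cutoff; undefined (error)
  when nothing tests positive.
* **Weighted kappa** — `1 − Σw·o / Σw·e` with linear (default) or
  quadratic disagreement weights; for binary ratings both reduce to
  unweighted Cohen's κ. Band labels: 0 < κ ≤ 0.20 slight, ≤ 0.40 fair,
  ≤ 0.60 moderate, ≤ 0.80 very good, ≤ 1 substantial; κ ≤ 0 is labelled
  "poor". The weighting is a configuration option, never chosen per
  dataset.
* **Group comparison** — one-way ANOVA per parameter (for two groups,
  F = t² of the pooled-variance t test, verified numerically), two-sided
  p-values, Bonferroni factor 3 for the three-parameter family, and
  t-based 95% CIs per group.

## Numerical and design choices

* Internal computation is in mm²/s; cohort tables and CSV reports use
  10⁻³ mm²/s, the convention of clinical diffusivity tables.
* Missing values are `NaN` inside volumes and are excluded from every ROI
  statistic.
* Determinism: every stochastic stage takes an explicit seed; identical
  seeds give bit-identical volumes, tables and CSV files (tested).
* Problem sizes in the tests and the acceptance script: the full
  48×48×24 phantom for fit-exactness, a 100×100 single-slice phantom
  (60 000 noise draws) for the Rician moment check, 10 000 subjects per
  group for the binormal-limit check, and 500 replicate 29/18 cohorts for
  replicate stability — all chosen to make Monte-Carlo error a small
  fraction of the tested tolerances while keeping a desk-scale run in
  seconds to a couple of minutes.
* The replicate-stability property (axial AUC > 0.85 in ≥95% of 29/18
  cohorts) sits near its own sampling noise: the generator's true
  proportion is ≈0.956, so the margin over 0.95 is real but thin by
  construction of the study conditions.

## Known limitations

* The phantom has no partial-volume mixing, distortions, or artifact
  voxels, and the cohort generator ignores cross-parameter correlation.
* Empirical clinical quantities from the motivating application (a
  particular cohort's AUC, cutoffs, or kappas) depend on that cohort's
  data and are not reproduced by simulation; the package reproduces the
  *methods* and the arithmetic worked examples exactly, and the
  generator-level quantities up to stated Monte-Carlo tolerances.
* Registration to other modalities (T1w-CE, FLAIR) is out of scope: all
  maps derived from one DTI acquisition are intrinsically co-registered,
  and masks must share the data grid exactly (no resampling).
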