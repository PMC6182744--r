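---
title: "Methods: subchondral bone texture and osteoarthritis progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subchondral bone texture and osteoarthritis progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific background

Trabecular bone in the subchondral plateau remodels early in knee
osteoarthritis: trabeculae thicken, coarsen, and lose their fine oriented
structure. On high-resolution MRI this remodeling changes the *texture* of
the bone signal before it changes anything a radiograph can measure. The
question this package operationalizes is whether statistical texture
features of subchondral bone — and their 12–18-month change — are
associated with subsequent radiographic progression, defined as a loss of
minimum medial joint space width (minJSW) of at least 0.7 mm over 36
months.

The analysis chain is:

1. **Texture features** over manually placed rectangular regions of
   interest (ROIs) in the medial tibia and medial femur: grey-level
   histogram moments, absolute gradient moments, run-length matrix (RLM)
   features, and grey-level co-occurrence matrix (GLCM) Haralick features —
   19 features per region in the default registry.
2. **Reproducibility screen**: a second analyst independently re-places
   ROIs on a subsample; features are retained only if the two-way
   random-effects absolute-agreement ICC is at least 0.8 *and* the
   root-mean-square coefficient of variation (RMSCV) is at most 10%, in
   both regions.
3. **Cohort construction**: progression classification from the minJSW
   trajectory, eligibility exclusions (missing minJSW, Kellgren–Lawrence
   grade 4, lateral-predominant joint space narrowing), and 1:1 optimal
   propensity-score matching of cases to controls on age, sex, BMI and
   baseline minJSW.
4. **Composite texture score**: repeated 10-fold cross-validated LASSO
   logistic regression on standardized features; odds ratios are reported
   per standard deviation of the composite score, with a Bonferroni gate
   (p < 0.008 for six models: tibial/femoral/combined × initial/change).

## Texture feature conventions

* **Quantization.** ROI intensities are min–max scaled to `1..2^bits`
  levels (6 bits for GLCM/RLM, 4 bits for gradients) with half-open bins
  whose top bin is closed. Min–max scaling makes every downstream feature
  invariant to affine intensity rescaling, which is the right behavior for
  MRI magnitude images with arbitrary scanner gain.
* **GLCM.** Co-occurrences are accumulated symmetrically (each ordered
  pair counted in both orientations) for four directions (0°, 45°, 90°,
  135°) and pixel offsets 1–5 — twenty configurations, averaged per
  feature. Entropies use the natural logarithm with the `0·log 0 = 0`
  convention.
* **RLM.** Maximal same-level runs along the four directions, restricted
  to in-ROI pixels; the Galloway features are normalized by the number of
  runs, and the run-pixel identity (total run length equals ROI pixel
  count) is enforced by construction and by test.
* **Gradients.** Central differences on the 4-bit quantized grid,
  evaluated only at interior pixels whose four neighbours are all inside
  the ROI.
* **Moments** are population moments (divide by *n*), kurtosis is excess
  kurtosis, and degenerate (constant) inputs report zero higher moments
  rather than NaN.
* Features are averaged across directions/offsets within a slice and then
  across the five slices of a series.

## Reproducibility statistics

`icc_single_absolute()` implements ICC(A,1) — two-way random effects,
absolute agreement, single measures — via explicit ANOVA sums of squares.
Absolute agreement is the correct flavour here because a systematic offset
between analysts is a real disagreement for a biomarker. `rmscv()` uses the
two-rater identity SD(a,b) = |a−b|/√2, divides by the pair mean, and
excludes subjects whose pair mean is within a relative epsilon of zero
(sign-crossing features would otherwise produce unbounded CVs). The screen
retains a feature only if it meets *both* thresholds in *both* regions;
boundary values (ICC exactly 0.8, RMSCV exactly 10%) are retained because
the exclusion is strict.

## Cohort, progression, and matching

`classify_progression()` applies the ≥ 0.7 mm minJSW-loss rule with a tiny
tolerance (1e-9 mm) so that a loss recorded as exactly 0.70 mm —
measurements carry 0.01 mm precision — is never misclassified by floating
point subtraction. Exclusions fire in a fixed precedence (missing minJSW,
then KL4, then lateral-predominant narrowing: lateral OARSI JSN strictly
greater than medial) and each subject receives one reason.

Matching minimizes the total absolute difference in propensity logits over
all 1:1 assignments, solved exactly with an in-package Jonker–Volgenant
linear assignment solver (verified against brute-force enumeration in the
tests). When a matched subject is later excluded for image quality, an
excluded *case* removes its pair, while an excluded *control* is replaced
by the nearest unused reserve control on the logit scale.

## Composite score and inference

`fit_lasso_cv()` selects the LASSO penalty by 10-fold cross-validated
misclassification error with class-stratified folds (guaranteeing both
classes in every training fold for small studies). `repeat_and_select()`
repeats this over `n_iter` fold draws and reports the iteration whose CV
error is closest to the mean (ties to the lowest index) as the
representative model; per-iteration cross-validated AUCs come from the
held-out prevalidated linear predictors.

Two conventions deserve a note:

* When the selected model has all-zero coefficients, its prevalidated
  predictor is a per-fold intercept that reflects fold composition, not
  signal; its CV AUC is therefore defined as 0.5.
* The association *inference* (odds ratio, confidence interval,
  likelihood-ratio p value) is computed by **split confirmation**
  (`split_confirmation()`): the model is selected on a stratified half of
  the subjects and the composite score is evaluated and tested on the
  held-out half. Testing the score on the same subjects used to select it
  — even with prevalidation — is anticonservative: in simulation the
  in-sample version rejected at far above the nominal rate on
  permuted-label data, while the split version holds the nominal level.
  The descriptive quantities (c-statistic, top features, subject scores)
  still come from the full-sample repeated-CV model.

Numerical settings in `cv.glmnet` (`nlambda = 50`,
`lambda.min.ratio = 0.01`, `thresh = 1e-5`) were chosen by verifying that
they reproduce the default path's selected penalty and fold errors on
representative problems at a fraction of the cost.

## The synthetic study generator

Real subchondral MRI is not redistributable, so the package ships a
generator whose defaults encode the study conditions: 61 cases and a pool
of 120 potential controls, five 256×256 slices per series, 23
duplicate-rated subjects, and covariates calibrated to the published
baseline table (age 64.5 ± 8 y, 42% female, BMI 31.2, baseline minJSW
3.8 mm, case minJSW change −1.29 mm).

Each slice is a thresholded Gaussian random field: white noise smoothed by
FFT with correlation length ℓ, thresholded at the target bone fraction,
and overlaid with Rician noise (magnitude MRI). ℓ is the single
*organization* knob — larger ℓ gives coarser, more disorganized-looking
trabecular texture and lower GLCM entropy. Case status can shift ℓ at
baseline and longitudinally (`effect = "modest"`, `"null"`, `"strong"`
presets); the `"null"` preset zeroes only the texture effect, leaving the
covariate structure intact. ROIs are rectangular bands on either side of a
mid-image joint line; the duplicate analyst sees the same images with ROI
edges jittered by at most one pixel.

**Scope and limitations.** The generator reproduces second-order texture
statistics well enough to exercise the pipeline and calibrate its error
rates; it is not a biomechanical model. It does not simulate MR physics
(no FISP sequence model, no field inhomogeneity), trabecular anisotropy,
or cartilage. Effect presets act through ℓ only, so generated group
differences are one-dimensional compared with real remodeling. Conclusions
about the *method* (calibration, recovery, reproducibility behaviour)
transfer; conclusions about biology do not.

Problem sizes in the tests (smaller images, single slices, reduced
repetition counts) are package choices made so the whole suite runs on one
CPU in minutes; the scientific defaults remain the full-size study
conditions.

## Reproducing the analysis

The numbered scripts under `analysis/` run the full default-condition
study end to end and write tables to `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort and baseline table
Rscript analysis/02_cohort.R          # exclusions, matching, balance
Rscript analysis/03_features.R        # texture extraction (long step)
Rscript analysis/04_reproducibility.R # ICC/RMSCV screen
Rscript analysis/05_association.R     # six-model association table
```

All randomness flows from the two seeds in `analysis/params.R`; rerunning
the chain reproduces every table byte for byte.
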