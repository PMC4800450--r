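---
title: "Localized and distributed neural codes as behavioral predictors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized and distributed neural codes as behavioral predictors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(neurocode)
```

# The analysis model

The package operationalizes two ways a cortical region can carry
information, and asks which of them explains individual differences in
behavior.

**Univariate (localized) code.** Per voxel, a faces-versus-objects contrast
yields a t statistic, converted to a standard-normal Z by p-value matching
(`t_to_z()`); the region's *overall face selectivity* is the arithmetic
mean of Z over ROI voxels. This measure rises when the region as a whole
responds more to faces than objects, regardless of which voxels do so.

**Multivariate (distributed) code.** The *between-category pattern
dissimilarity* is `1 - r` between the spatial beta patterns for faces and
objects (betas averaged across runs), after subtracting each voxel's mean
beta across all scan categories. This mean-pattern ("cocktail-blank")
removal strips the regional mean response so the measure reflects the
geometry of the pattern, not its amplitude. The measure is bounded in
[0, 2]; larger values mean the face pattern is more distinct from the
object pattern.

**Noise control.** If a subject's data are noisy, *any* two patterns look
dissimilar, so a brain-behavior correlation with between-category
dissimilarity could reflect noise rather than representational geometry.
The *within-category dissimilarity* — `1 - r` between run 1's and run 2's
face patterns, an inverse test-retest reliability — indexes that noise and
enters the battery both as a correlate and as a regression covariate.

The inferential battery on top of the measures:

* Pearson correlation per (measure, behavior) pair, two-tailed p from
  `t = r sqrt((n-2)/(1-r^2))`.
* Steiger's Z in the Meng–Rosenthal–Rubin form for comparing the two
  dependent correlations that share a behavioral score (`steiger_z()`),
  one-tailed. The MRR variant is pinned deliberately: at the battery's
  published inputs (r12 = 0.27, r13 = 0.12, r23 = 0.34, n = 165 and
  r12 = 0.22, r13 = 0.10, r23 = 0.34, n = 165) it reproduces the reported
  Z = 1.71 and Z = 1.36 to within 0.01; Steiger's (1980) Z*2 rounds to the
  same values at these inputs, so the choice is not empirically
  distinguishable here and only one form is exposed.
* OLS regression with standardized coefficients for covariate control
  (gender, object-recognition accuracy, the competing neural measure, the
  noise index). Gender is coded female = 1, male = 0 so that a female
  advantage on expression recognition appears as a positive coefficient.
  No multiple-testing correction is applied anywhere, mirroring the
  battery's reporting conventions.
* Balanced fourfold cross-validated prediction with a permutation null
  (below).

# Cross-validated predictability

Correlation overfits in the sense that the same data select and evaluate
the association. The battery therefore re-expresses each association as
out-of-sample predictability:

1. Subjects are partitioned into `k = 4` near-equal folds at random,
   redrawn (up to `max_restarts`) until a Kruskal–Wallis test across folds
   finds `p > 0.05` for **both** the predictor and the response. The test
   and the both-variables rule are design choices: the balance requirement
   is stated distributionally, and a rank-based k-sample test applies it
   without distributional assumptions.
2. For each fold, a simple linear regression fitted on the other three
   folds predicts the held-out fold. Concatenating predictions gives
   `r(prediction, observation)`.
3. The predictor is shuffled `B = 5000` times (folds held fixed — the
   permutation scheme shuffles only the independent variable); each shuffle
   reruns step 2, and `p = (# null r >= observed r) / B`.

Numerical notes, all verified by tests:

* The paper-literal p can be exactly 0; `smoothed = TRUE` gives the
  `(count+1)/(B+1)` estimator, which is the better-calibrated choice and
  the one we recommend when p feeds further computation.
* Under the null, `r(prediction, observation)` is *negatively* biased
  (about −0.08 at n = 160, k = 4): each held-out fold's responses are
  anti-correlated with the training mean that serves as the prediction
  intercept. The permutation test is unaffected — its null distribution
  carries the same bias — but the point estimate should not be read as a
  correlation centered on zero under independence.
* The permutation test's type-I error at one-tailed alpha = 0.05
  calibrates to 0.05 +/- 0.02 (200 null replicates, B = 500 in the test
  suite), and the Steiger test to 0.05 +/- 0.01 (10,000 null draws).

# The synthetic cohort generator

`generate_cohort()` draws cohorts in which the two brain-behavior effects
are planted through *independent* latent channels, so the double
dissociation is structural:

* Latent amplitude `a_i ~ N(3, 1)` (contrast-Z units) drives the mean face
  response: the per-voxel contrast Z is `a_i` plus noise, so overall
  selectivity estimates `a_i` almost noiselessly at 200 voxels.
* Latent separation `s_i ~ N(0.8, 0.25)` clipped to [0, 2] sets the angle
  between face and object patterns: the object pattern is a unit-RMS
  zero-mean direction `u1`, the face pattern `cos(theta) u1 +
  sin(theta) u2` with `cos(theta) = 1 - s_i`. The remaining categories are
  constructed so the true category-mean pattern is constant across voxels,
  which makes the mean-removed face/object correlation exactly
  `1 - s_i` in the noiseless limit — the planted separation *is* the
  population dissimilarity.
* The expression score is `24 + 3 (rho_se z_a + b z_g + e)` rounded to an
  integer in 0–36; the identity accuracy is `0.78 + 0.09 (rho_di z_s + e)`
  clipped to [0, 1]; flower accuracy is `0.81 + 0.08 e` (scales chosen to
  match the published score summaries). The gender loading `b` is solved
  from the target within-group Cohen's d (default 0.58, P(female) = 0.6)
  inside the unit variance budget, so the planted correlation between the
  latent and the score equals `rho` exactly in population. Planted
  defaults: `rho_selectivity_expression = 0.22`,
  `rho_dissim_identity = 0.27`, behavioral cross-correlation 0 (the
  battery's source does not report it; it is configurable via
  `rho_behavior`).
* Measurement: per run and voxel, i.i.d. Gaussian noise with
  `noise_sd = 0.3` on unit-RMS patterns — about the level that leaves the
  run-averaged pattern correlation with ~3 runs at a reliability where
  recovered cohort correlations stay within a few hundredths of the
  planted values (the tests require the mean recovered r across 200
  cohorts of n = 165 to be within 0.05 of the planted 0.22 / 0.27; the
  realized means are ~0.214 and ~0.27).

What the generator does **not** emulate: temporally autocorrelated fMRI
noise, physiological confounds, head motion, ROI-identification failure
(every synthetic subject has an ROI; the exclusion machinery is exercised
through degenerate-pattern fixtures and the volumetric path), spatial
smoothness, or between-region structure. Passing tests therefore validate
the *analysis machinery and its calibration under the stated generative
model*, not robustness to realistic fMRI artifacts.

`generate_bold()` adds a minimal volumetric path — a spherical blob in a
small grid responding to the face condition through the block-design GLM —
used to test design construction, beta recovery, t→Z conversion, and
connected-component ROI extraction against ground truth masks.

# GLM and ROI choices

* HRF: single gamma with shape 4, scale 1.5 s (peak lag 6 s, dispersion
  3 s) — the conventional single-gamma of the major analysis packages; the
  parameters are exposed in `design_spec()`. Boxcars are convolved on a
  0.1 s grid and sampled at volume times; the temporal derivative is the
  finite-difference slope on that grid.
* t→Z via two-sided p-value matching on the log scale; this is exact at
  every df rather than the `Z ≈ t` approximation (which is off by ~0.03 at
  df = 200, t = 3 — a test documents the convergence).
* Degenerate fits are explicit: an exact fit (residual variance at
  rounding level, thresholded at `1e-20` relative to the fitted scale) with
  a nonzero contrast yields `Inf` with a warning; a contrast at rounding
  level relative to its betas is reported as exactly 0.
* ROI extraction: breadth-first connected components over a configurable
  neighborhood (default 26-connectivity, the most permissive standard
  choice), threshold Z > 2.3, with a small seed-search radius. "ROI not
  identified" is a normal outcome, not an error; such subjects are
  excluded listwise and logged, and the pipeline reports the
  identification rate.
* Mean-pattern centering defaults to **all four** scan categories.
  Centering over exactly the two compared categories is rejected by
  default because it is algebraically degenerate: the centered vectors are
  exact negatives, forcing dissimilarity = 2 for any non-identical input
  (a test demonstrates this), so it cannot be a meaningful choice.
* A single GLM over concatenated runs with run-wise intercepts is the
  natural default for contrast maps; per-run fits remain available through
  `fit_glm()` on run-wise slices (the simulated pattern matrices carry
  per-run betas directly).

# Problem sizes in the test suite

The suite favors exact oracles (closed forms, hand-rolled arithmetic,
explicit `lm` loops, graph-component comparisons) at tiny n, plus
calibration simulations sized for stable Monte-Carlo error: 200 cohorts of
n = 165 for effect recovery, 100 replicates for the double-dissociation
rate, 200 null replicates at B = 500 for permutation type-I error, 10,000
draws for Steiger calibration, and 60 cohorts at B = 300 for the
shrinkage/power property. `scripts/acceptance.R` re-simulates 200 cohorts
of n = 165 per run.

# Known limitations

* The generator's linear-Gaussian latent-to-score link matches the
  battery's Pearson/OLS machinery by construction; nonlinear or
  heteroscedastic brain-behavior links are out of scope.
* Only univariate (single-predictor) cross-validated prediction is
  implemented; regularized or multivariate predictive models are
  non-goals, as is classification-based decoding (the motivating design
  separates scan stimuli from behavioral tasks, which precludes per-stimulus
  estimates).
* Folds are held fixed during shuffling by default, following the
  battery's literal permutation scheme; `permutation_p(rebalance = TRUE)`
  redraws a balanced partition per shuffle for sensitivity analysis, at a
  substantial cost in runtime.
* NIfTI I/O is a thin optional wrapper (RNifti); spatial preprocessing
  (motion correction, smoothing, normalization, high-pass filtering) is
  deliberately absent.
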