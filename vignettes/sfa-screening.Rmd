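---
title: "Structure-function association models for cognitive screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function association models for cognitive screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models it fits,
the assumptions they rest on, the choices made where the design was
genuinely open, and what the synthetic testbed does and does not establish
about real data.

## The screening model

The pipeline rests on one biological premise: the mapping from regional
brain structure to cognitive performance (the structure-function
association, SFA) is *cohort-specific*.  Normal aging, MCI and Alzheimer's
dementia damage different cell populations and regions, so a regression
trained on one cohort encodes a pattern that fits members of that cohort
better than outsiders.

**Regression.** For each cohort $g$ and test $t$ we fit ridge coefficients

$$\hat w_{gt} = \arg\min_w \lVert y - Xw - b \rVert^2_2 + \alpha\lVert w \rVert^2_2,
\qquad \alpha = 0.5,$$

on that cohort's records only.  Features are z-scored inside the training
set (ridge is not scale-equivariant; volumes in % of TIV, thickness in mm
and area in mm² live on very different scales) and the intercept is
unpenalised, the standard convention.  The solution is computed by QR on
the $\sqrt\alpha$-augmented design, which is numerically gentler than the
normal equations; the test suite cross-checks it against the closed-form
penalized normal equations to $10^{-8}$ on random designs.  $\alpha$ is a
user parameter but deliberately not tuned: the point of the models is a
stable per-cohort stamp, not maximal predictive accuracy.

**Classification.**  Given a subject's features and observed score, each
cohort model issues a prediction; the absolute residual
$r_g = |\hat y_g - y|$ is the misfit of cohort $g$'s stamp.  The smallest
residual wins the test's vote, and the majority over the voting tests
(default MMSE, ADAS-13, RAVLT immediate — the trio under which vote fusion
works best; all five tests are supported) gives the final label.
Predictions are *not* clipped to scale bounds before residuals are taken:
clipping would collapse distinct model predictions onto the bound and
destroy the residual geometry the comparison relies on.

Two tie-break levels had to be defined, since min-residual rules admit
exact ties:

* *per-test ties* (residuals equal within $10^{-9}$): the less severe
  label wins (CN over MCI over Dementia) — for a screening instrument a
  tie should not manufacture pathology;
* *vote ties*: among the tied leading labels, the vote cast with the
  smallest *range-normalised* residual wins.  Normalisation by the test's
  empirical range makes residuals comparable across tests with spans of
  ~18 points (MMSE) and ~270 seconds (TMT-B).

Both tie-breaks are recorded in the output (`tie_broken`).

**Evaluation.**  Model error is reported as the mean absolute error of
repeated subject-grouped k-fold cross-validation (default 10 × 10).
Grouping folds by `subject_id` keeps repeat visits of one person on one
side of the split.  The reported `mae_se` is the standard error of the
per-fold MAEs and the 95% CI is $\pm 1.96$ SE; with 100 fold MAEs that CI
is tight, which matches how such tables are usually printed.  The protocol
(folds × repeats, seed) is configurable because nothing in the method pins
it down.

**MAE/range.**  To compare errors across scales, MAE is expressed as a
percentage of the test's *empirical pooled* range (max − min over all
cohorts), not the nominal scale span.  The choice matters: in an elderly
clinical population MMSE occupies about 18 of its 30 nominal points, and
published MAE and MAE/range pairs are mutually consistent only under the
empirical reading — solving the implied range from one cohort's pair
reproduces the other cohorts' percentages to rounding, a check the
acceptance suite automates.  A `range = "nominal"` fallback exists for
degenerate samples.

## The synthetic cohort generator

Access to the clinical cohorts this design targets is controlled, so the
package carries a generator whose defaults *are* the study conditions, and
whose internals are known exactly — every downstream stage is tested
against planted truth.

**Calibration targets.**  Cohort sizes 287/646/369 (CN/MCI/Dementia), ages
uniform on 55–90.  Score intercepts and SDs per cohort match published
ADNI1 cohort descriptive statistics (e.g. MMSE 29.06 ± 1.09 / 26.91 ± 2.2
/ 22.66 ± 3.03); within-cohort age slopes equal the published CN estimates
plus the group interaction terms (so MMSE/ADAS-13 trends are essentially
flat within cohorts, while DSST declines at −0.616 points/yr in CN and
TMT-B rises at 2.126 s/yr).  Sex ratios and education distributions follow
the same source.

**The convergence constraint.**  The processing-speed trendlines of the
three cohorts converge at roughly 100 years of age.  The published cohort
means, the published slopes, and a single convergence age cannot all hold
exactly simultaneously (the dementia TMT-B mean of 200.96 s with the
published slopes would put the intersection nearer 120 years).  The
generator prioritises the slope structure and the convergence property,
because both are properties the analytics must demonstrably recover:
for DSST and TMT-B the CN line is anchored at the CN cohort mean and the
MCI/dementia intercepts are derived from a common intersection at
`convergence_age = 100`; MMSE, ADAS-13 and RAVLT intercepts use the cohort
means directly.  The implied dementia TMT-B intercept (≈150 s) is lower
than the observed cohort mean — a documented cost of making the three
constraints coherent.

**Latent structure.**  A single gray-matter axis (GM %TIV) declines with
age at a cohort-specific rate (−0.153 %/yr in CN, flatter in MCI and
dementia, converging like the test scores) with between-subject SD
`atrophy_sd = 1.5` %TIV.  All 113 features derive from it: GM volumes
proportionally, ventricles inversely, cortical thickness and surface area
with small positive loadings, plus independent Gaussian measurement noise
of 5% of each feature's baseline.  Feature dimensionality (45 VBM + 68
SBM named columns) mirrors the FreeSurfer-derived registry so synthetic
and real data share every code path.

**Scores.**  Each score is

$$y = \mu_{gt} + s_{gt}(\text{age} - 72.5) +
      w_{gt}^\top\,(f - \mathbb E[f \mid \text{age}, g]) + \varepsilon,$$

clipped to the nominal scale bounds.  Two deliberate choices here:

* The SFA weights act on the *age-detrended feature deviations*, not on
  raw features.  Raw-feature weights would shift every cohort mean by
  $w^\top \mathbb E[f]$ and add the features' own age trend to the score
  trend, corrupting exactly the calibrations above; detrended weights
  leave means and slopes identical to their targets while still planting a
  cohort-specific structure-function coupling (a subject more atrophied
  than expected for their age scores worse, in a cohort-specific way).
* Weight patterns are anatomically flavoured (memory tests load on
  hippocampal/entorhinal structures, processing speed on fronto-parietal
  cortex and white matter) with a cohort tilt scaled by `separation`
  ($\delta$): normal aging emphasises fronto-parietal structures, MCI
  mesial-temporal ones, dementia a widespread temporo-parietal set.
  $\delta = 0$ plus equalised cohort rows (`null_sim_config()`) makes the
  three cohorts exchangeable — the classifier's chance calibration.

Weights are rescaled so the morphometric signal explains
`signal_fraction = 0.15` of each score's variance, the residual noise
making up the rest so total SDs match the targets.  The value is modest on
purpose: published per-cohort MAEs are close to $0.8\times$ the cohort
score SDs, implying the real within-cohort coupling is weak and the
classifier's power comes mostly from between-cohort differences.  The
generator reproduces that regime rather than an optimistic one.

**Clipping.**  Scores are clipped, not resampled, at the scale bounds —
simpler, and the induced bias is handled where it matters: the CN MMSE
distribution (29.06 ± 1.09 against a ceiling of 30) loses ≈0.12 points of
mean to one-sided clipping, so the generator solves the latent pre-clip
mean per (cohort, test) by `uniroot` on the closed-form clipped-normal
expectation, averaged over the age grid, such that the *realised* cohort
mean equals the configured one.  Residual clipping effects remain in
higher moments (the realised CN MMSE SD is ≈0.85 rather than 1.09) and in
slight attenuation of slopes of heavily clipped scores (TMT-B tails); the
slope-recovery checks are therefore run on large samples against standard
errors, where the attenuation (≲5%) is well inside the bands.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: longitudinal within-subject correlation
(visits are independent records), feature covariance beyond the single
atrophy axis (real parcellations have rich region-region structure),
non-Gaussian and heteroscedastic score residuals, missing-data patterns,
site/scanner effects, and diagnostic label noise.  The generator
establishes that the *pipeline* recovers known structure; transfer to
clinical data rests on the published results it is calibrated to.

## Feature importance and correlations

Four tree ensembles — Random Forest, Extra Trees, AdaBoost.R2 and gradient
boosting — are fitted per (cohort, test) and their impurity/gain
importances, each normalised to sum to one, are averaged (the fusion rule
had to be chosen; the arithmetic mean keeps every ensemble's vote equal).
Conventions follow the scikit-learn-style regressors this design mirrors:
forests consider all features at every split (randomness lives in the
bootstrap and, for Extra Trees, in random cut points), boosting uses
depth-3 trees, and AdaBoost.R2 — implemented in-package on rpart learners,
with surrogate splits disabled so importance credit cannot leak to
correlated bystanders — down-weights rounds by their weighted loss.  All
fits are seeded and single-threaded, and feature columns are sorted by
name before fitting, so rankings are deterministic and invariant to column
order.  Ensemble sizes (500 trees, 200 boosting rounds, 50 AdaBoost
rounds) are fixed documented defaults.

Region-score association tables use Pearson correlation per cortical
parcellation volume with two-sided p-values, flagged at $p < 0.05$
uncorrected by default; a Benjamini-Hochberg option exists because 34
regions per table invite multiplicity concerns, but the uncorrected flag
matches how such cortical maps are conventionally thresholded.

## Trend analytics

Within-cohort trendlines are OLS of outcome on age (age centred at the
pooled mean for stability; intercepts are reported at age 0 so two fits
intersect by a one-line formula).  Slope comparisons between cohorts fit
`outcome ~ age * group` on the two-cohort subset, reference-coded; the
age-by-group coefficient *is* the slope difference, algebraically equal to
the difference of separate per-cohort fits — an identity the tests assert.
The estimate ± SE with a 95% CI and p-value mirrors the layout such
interaction tables are printed in.  Convergence ages come from the exact
two-line intersection, with slopes equal within $10^{-9}$ mapped to "no
intersection" rather than a numerical explosion.

Cohort comparison tests follow the conventional pairing — Kruskal-Wallis
for continuous variables, chi-square on the cohort-by-category table for
categorical ones.  (Descriptions of this battery sometimes transpose the
two names; the package implements the tests by their definitions and takes
no position on intent.)

Degenerate inputs are defined, not crashed on: two-point trends are exact
fits with an `NA` slope SE and a warning; constant-age subsets are
singular-fit errors; single-valued scores give a zero empirical range with
MAE/range flagged undefined.

## Problem sizes and determinism

The test-suite and acceptance problem sizes are chosen so the full suite
runs in a couple of minutes while keeping every statistical band wide
relative to its Monte-Carlo error: 300 subjects per cohort for classifier
recovery and null calibration (the ±2-binomial-SD chance band at n = 300
spans 23.3–43.3%), 20 train/test replicates for noisy-recovery averages,
200 replicates of n = 100 per cohort for CI-coverage checks (coverage
bands [90%, 99%]), and n = 3000 per cohort for single-shot slope recovery
within 3 SE.  Every stochastic step is driven by an explicit seed: the
generator's RNG state is set from its config, cross-validation folds from
the evaluation seed, and each ensemble from its own derived seed, so all
results are bit-reproducible.

## Known limitations

* The classifier is a screening aid, not a diagnostic: in the calibrated
  regime the intermediate MCI class is recovered at ~50% TPR (well above
  the 33% chance level but far from clinical certainty), consistent with
  MCI being the hardest class in practice.
* $\alpha$ is fixed rather than tuned; no nonlinear SFA models are
  offered.
* The evaluation treats visits as independent records; subject-grouped
  folds prevent leakage but no mixed-effects structure is modelled.
* Empirical score ranges make MAE/range sample-dependent; comparisons
  across datasets should use a common range.
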