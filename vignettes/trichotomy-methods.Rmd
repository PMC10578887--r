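---
title: "Methods: composite axes, cutoff-anchored normalization, and the eight-subgroup trichotomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite axes, cutoff-anchored normalization, and the eight-subgroup trichotomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichotomy)
```

## The problem

Mixed dementia — Alzheimer's disease (AD) pathology together with vascular
disease (VD) — is common at autopsy but hard to diagnose in life, because a
clinical label like "mild cognitive impairment" says nothing about which
pathology drives the impairment. The trichotomy framework replaces the
clinical label with three continuous biomarker axes:

* **ADF** — the Alzheimer's disease factor, `log10(pTau/Abeta42)` from CSF.
  Low amyloid-beta and high phosphorylated tau both push the ratio up.
* **VDF** — the vascular disease factor, a unit-norm linear combination of
  two diffusion-MRI white-matter markers:
  `0.135*log10(PSMD*1e4) + 0.991*log10(mFW*1e2) - 1.474`.
* **Cog** — a cognition composite, `-0.076*ADNI_EF - 0.997*ADNI_MEM + 0.519`,
  oriented so that larger means worse cognition.

Each axis carries a cutoff `cth` on its raw scale: `log10(0.022)` for ADF
(from an independent CSF-vs-amyloid-PET calibration) and 0 for the two
LDA-derived axes. After normalization (below), an axis is *positive* when
its score exceeds 0.5, and the three signs place every subject into one of
eight biologically defined subgroups (`bMX`, `bAD`, `bVD`, `bCL`,
`bCN_MX`, `bCN_AD`, `bCN_VD`, `bCN`), including the clinically elusive
mixed-dementia and preclinical groups.

## Deriving axes by linear discriminant analysis

`fit_lda_axis()` reproduces how the VDF and Cog axes were constructed:
two-class Fisher LDA with pooled within-class covariance and equal priors.
The weight vector is `w ∝ S⁻¹(μ_patient − μ_control)` rescaled to unit
Euclidean norm, and the intercept places the decision boundary at the
projected midpoint of the class means, so the cutoff is exactly 0 and the
patient class projects positive. Unit-norm coefficients make the raw score
a signed geometric distance from the boundary; both published coefficient
vectors satisfy this convention to within 0.001.

Equal priors and the midpoint boundary are design choices: priors are not
part of the published rule, and the midpoint boundary is the unique choice
that makes `cth = 0` meaningful for balanced and unbalanced samples alike.
A singular pooled covariance (e.g. duplicated features) is handled with a
small ridge (`1e-6` times the mean diagonal) and a warning; identical class
means are a hard error. `loocv_accuracy()` refits the axis with each
subject held out, the stability check used for the cognition axis, and
`classification_accuracy()` is the plain thresholded-agreement rate.

## The uniform normalization transform (UNT)

Raw axes have incommensurate scales. The UNT maps each raw score into
(0, 1) monotonically with the cutoff anchored at exactly 0.5, so the
trichotomy threshold means the same thing on every axis.

The construction here is a piecewise-affine rescaling of the empirical CDF.
With `F` the midrank empirical CDF of the calibration sample (tabulated at
the sorted unique values with the `(rank − 0.5)/n` convention, linearly
interpolated) and `F0 = F(cth)`:

$$
\mathrm{CSnorm}(x) = \begin{cases}
0.5\,F(x)/F_0 & x \le c_{th} \\
0.5 + 0.5\,\dfrac{F(x) - F_0}{1 - F_0} & x > c_{th}.
\end{cases}
$$

This is the minimal table-based map with the three properties the method
needs: values strictly inside (0, 1), the cutoff at exactly 0.5, and
approximate uniformity on each side of the cutoff. It is deliberately
nonparametric — no density model is assumed — and should be read as a
reconstruction of the normalization from those three properties rather
than a transliteration of any particular reference implementation.
Consequences that the test suite checks directly:

* rank correlation between raw and normalized scores is exactly 1;
* the fraction of calibration subjects above 0.5 equals the fraction with
  raw score above `cth` (mass preservation), which in turn makes subgroup
  positivity identical whether computed on raw or normalized scores;
* within each side of the cutoff the normalized calibration scores are
  uniform on their half-interval (Kolmogorov–Smirnov distance below
  `1.36/sqrt(n_side)` in ≥95% of synthetic calibrations).

Numerical details: ties get midranks; a calibration sample needs at least
20 finite values and more than one distinct value; the cutoff must lie
strictly inside the calibration range ("cutoff not bracketed" otherwise).
Tables are fitted once, serialized as two-column text with 17 significant
digits (bit-exact reload), and applied to new subjects without refitting.
New scores outside the calibration range clamp to `epsilon = 1/(2n)` and
`1 − epsilon` with a warning — symmetric with the CDF convention, and
keeping outputs in the open interval. A subject exactly at the cutoff is
factor-negative, matching the "Cog ≤ 0.5" vs "Cog > 0.5" split; the same
boundary rule applies to all three axes.

## Reported percentages

Prevalence and membership percentages are rounded half-away-from-zero to
one decimal. This matches the published reporting style; note 73/538 =
13.57% prints as 13.6% under this rule (some summaries elsewhere print
13.5% for the same count, which is truncation rather than rounding).

## The statistics battery

* `residualize()` / `partial_correlation()`: OLS residualization on a
  shared covariate set (intercept always included, categorical covariates
  expanded to indicators; default covariates age, sex, education,
  protocol), then Pearson correlation of the residual pairs with a
  t-distributed p-value on `n − 2 − k` degrees of freedom. The regression
  slope and its standard error come from the joint OLS fit, so beta and
  the residual correlation can legitimately differ in sign when covariates
  absorb shared variance; both are reported.
* `compare_models_aic()`: `R² = 1 − RSS/TSS` and
  `AIC = n·ln(RSS/n) + 2(k+2)`, the Gaussian-likelihood form counting the
  intercept and error variance. The AIC constant convention matters only
  for differences, which are convention-free. Standard `R²` never
  decreases under nesting; AIC is the quantity that can prefer the smaller
  model. AIC with its fixed penalty of 2 is not a consistent selector:
  with one spurious predictor it keeps the true model with probability
  `P(χ²₁ < 2) ≈ 0.84` regardless of sample size, and the tests assert that
  rate rather than a near-certain selection.
* `group_pair_tests()`: nine subgroup-pair contrasts (G1–G9: marginal
  contrasts on each axis plus conditional contrasts within strata) crossed
  with nine hypotheses over the six auxiliary variables not used in the
  composites. Proportions (sex, APOE4, CDRSB, ΔCDRSB/year) are compared by
  chi-squared test *without* continuity correction; means (hippocampal
  volume, brain atrophy) by pooled-variance two-sample t-test, with Welch
  available via `welch = TRUE`. Both choices are stated here because the
  published description does not pin them down. Raw p-values are
  multiplied by the battery size (9 × 9 = 81, Bonferroni) and capped at 1.
  A 2×2 table with an empty cell is reported as untestable rather than as
  a p-value. The default hypothesis set (one sex contrast, two APOE4
  thresholds, two CDRSB thresholds, two ΔCDRSB thresholds, two means) is a
  package default chosen to span the six variables with nine tests; any
  list with the same element structure can be substituted.

## The synthetic cohort generator

`generate_cohort()` exists so every pipeline stage is testable with known
ground truth. It is a latent-state model, not a copy of any real cohort's
marginals: independent Bernoulli AD and VD states shift log10-scale
biomarker locations; within-modality pairs (Abeta42–pTau, mFW–PSMD,
memory–executive) are correlated through shared Gaussian factors; the
cognition composites are linear in both latent states plus an age term and
correlated noise, with AD hitting memory harder and VD hitting executive
function harder — the qualitative cross-correlation pattern the real
biomarker table shows. Clinical labels (aCN/aMCI/aAD) derive from the
noise-free cognitive severity plus rater noise.

Default parameters were fixed once, by normal-tail arithmetic on the axis
formulas, so that the *classified* composition is ADNI-like — roughly 40%
AD-factor-positive, 18% VD-positive, and a clinical mix near 53/35/13% —
with realistic between-group overlap (healthy subjects sit only ~1–2
pooled SD below the ADF and VDF cutoffs, so some misclassification against
the latent state is expected and intended). The generator does **not**
emulate inclusion/exclusion criteria, scanner artifacts beyond a
categorical protocol covariate, missingness mechanisms, or longitudinal
structure; passing tests therefore demonstrate pipeline correctness under
the stated generative model, not performance on real ADNI exports.

The recovery tests use an explicit *strong-effect* configuration (every
axis separates its latent classes by ≥4 pooled SD, cognition noise 0.2):
under those conditions the full chain — fit LDA axes, calibrate the UNT,
classify — must assign at least 90% of 2000 subjects the label implied by
their latent truth triple. Family-wise error of the 81-test battery is
checked over 500 null replicates at n = 240 with labels drawn independently
of every tested variable.

## Worked example

```{r example, eval = FALSE}
sim <- generate_cohort(cohort_config(n_subjects = 538, seed = 1))
res <- run_pipeline(sim$cohort, pipeline_config())
res$prevalence
res$crosstab
partial_correlation(
  compute_cog_raw(sim$cohort$adni_mem, sim$cohort$adni_ef),
  compute_vdf_raw(sim$cohort$mfw, sim$cohort$psmd),
  data.frame(adf = compute_adf_raw(sim$cohort$abeta42, sim$cohort$ptau)),
  names = c("Cog", "VDF"))
```

## Known limitations

* The normalization is calibration-dependent: a table fitted on one cohort
  and applied to another preserves the *cutoff* interpretation but not
  conditional uniformity on the new cohort.
* Axis cutoffs are inherited from their source populations; the ADF
  constant in particular was calibrated on a largely white, highly
  educated research population.
* The generator's latent states are binary; real pathology loads are
  continuous, so "label recovery" is a cleaner notion here than it would
  be on real data.
* No longitudinal modeling: subgroup transitions over time are out of
  scope.
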