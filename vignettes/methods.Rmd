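---
title: "Methods: matched-cohort estimation of accelerated brain aging in T2DM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-cohort estimation of accelerated brain aging in T2DM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(T2DMAging)
```

## The question and the estimation strategy

Type 2 diabetes mellitus (T2DM) is associated with cognitive deficits and
gray-matter atrophy. The scientific question this package operationalizes
is whether those deficits look like a disease-specific degenerative
pathway or like ordinary brain aging arriving early. Three quantities
carry the answer:

1. **Matched effect maps** — the per-domain / per-region coefficients of
   T2DM status in OLS models fit on exactly matched case–control samples,
   and the corresponding coefficients of age in non-diabetic samples.
2. **Overlap** — the Pearson correlation between the T2DM and age
   coefficient vectors across the 45 bilateral gray-matter regions (or
   cognitive domains). High overlap means the disease reuses the aging
   topography.
3. **Acceleration** — within diabetic subjects, the ratio of the
   disease-duration slope to the age slope of whole-brain gray matter
   volume. A ratio of 0.26 reads as "each year of disease adds 0.26 years
   of typical volumetric aging".

Everything is cross-sectional: the models compare people, not trajectories
of the same person, which is the central caveat for causal readings.

## Cohort rules and matching

Eligibility precedes matching, in a fixed order so that exclusion counts
are reproducible: (i) females who do not report menopause, or report
ongoing hormone therapy, are excluded (the sample starts at age 50, where
menopausal transition is a plausible confound; a missing menopause report
counts as not reported); (ii) diabetic subjects whose mean self-reported
onset age is below 40 years are excluded, a standard guard against type 1
diabetes contamination; exactly 40 is retained. Hypertension is labelled
from measured pressure (SBP > 140 or DBP > 90 mmHg, strict inequalities);
a missing measurement propagates as a missing flag rather than
"normotensive", removing the subject from matching rather than
misclassifying them.

Matching is 1:1 and exact on integer age, sex, education (degree / no
degree) and hypertension. Exact keys make compatibility an equivalence
relation, so strata can be paired greedily in sorted-id order and the pair
count per stratum, min(#cases, #controls), attains the maximum bipartite
matching size — the suite checks this against an independent brute-force
matcher. Sorted-id pairing is our determinism choice; how surplus controls
were discarded in the motivating analyses is generally unstated, and any
rule that respects the strata yields the same pair count. The medication
contrast (metformin-only vs unmedicated diabetics) uses the same machinery
with coarse keys — half-open bins `[origin + j·w, origin + (j+1)·w)` with
w = 5 years for age and 3 years for duration, origin 0 — and adds BMI as a
regressor, the available proxy for disease severity.

## Effect models and their percent scaling

All effects are OLS coefficients with t-based two-sided tests and 95%
CIs (the OLS point estimate is the Gaussian maximum-likelihood estimate;
t-based intervals keep inference consistent at small residual df). After
exact matching, models default to the factor alone; covariates are
configurable. Percent effects divide the coefficient and its CI bounds by
the matched control-arm mean (for continuous factors such as age, by the
sample mean), which makes results unit-free; the suite checks invariance
under rescaling of the outcome. Regional volumes are first divided by the
subject's head-size scaling factor. Bonferroni correction (family size 45
for regions, the domain count for cognition) applies to structural and
cognitive maps; Benjamini–Hochberg FDR to voxelwise activity.

## ALFF

Each voxel's time series is linearly detrended and Fourier transformed;
the amplitude is the mean over in-band bins (0.01–0.08 Hz, inclusive
edges, unpadded DFT) of √2·|X(f)|/N — a pure in-band sinusoid of amplitude
A at an exact bin contributes its RMS A/√2 to the band mean. The absolute
normalization constant is immaterial because maps are divided by the
subject's in-mask global mean (in-mask mean exactly 1 afterwards), making
all downstream statistics invariant to global signal scaling. Detrending
makes the amplitude exactly invariant to constant offsets and linear
drifts; it also means a pure off-band sinusoid is rejected to numerical
precision only when it is orthogonal to the trend basis (the calibration
tests use midpoint-symmetric cosines for this reason).

Smoothing is separable Gaussian, σ = FWHM/(2√(2 ln 2)) per axis in voxel
units, kernel normalized to unit mass and renormalized by the smoothed
support indicator, so a uniform field is exactly preserved including at
edges and NA voxels stay NA. We smooth the ALFF maps (then restore the
unit-mean invariant); smoothing the 4D series before amplitude computation
is the other common order and is available by smoothing inputs — for
group statistics on synthetic data the two differ only in effective SNR.

Group inference fits the shared-design OLS per voxel, converts the factor
t to a signed z by two-sided tail matching (comparable across differing
df), computes two-sided voxel p-values, BH-adjusts across in-mask voxels,
keeps voxels with adjusted p ≤ q = 0.05, groups them by face
(6-neighbour) connectivity — connectivity is unstated in common pipelines;
face adjacency is the conservative choice — and discards clusters below
12 voxels. Cluster sets grow monotonically with q by construction.

## The Fieller acceleration interval

Both slopes come from one joint model (volume ~ age + duration) within
diabetic subjects, which supplies the coefficient covariance v₁₂ the
Fieller set needs; fitting two marginal models would force an assumption
about that covariance. The confidence set is the solution of a quadratic
inequality and is an interval exactly when the age slope is significantly
nonzero; otherwise the set is reported unbounded or exclusive with a flag
rather than silently truncated. Critical values use the exact t quantile
at every df (indistinguishable from the normal beyond a few hundred df).
The suite verifies the closed form against a grid-scan/root-refinement
oracle of the inequality and checks convergence to the delta-method
interval when the denominator is precise, plus empirical coverage.

Duration is age minus the mean of up to three per-visit self-reported
onset ages. Reporting noise (integer-rounded Gaussian, SD 1 year,
truncated at the visit age) makes measured duration an errors-in-variables
regressor and attenuates the ratio by about 1% at the default duration
spread — visible in the acceptance simulations, which therefore regress on
the generator's true duration when the target is the calibration of the
estimator itself; the attenuated variant is what a real analysis would
report. Whether the age slope should come from the within-T2DM joint fit
or from healthy controls is ambiguous in practice; the joint fit is the
default (it keeps the covariance honest), and the HC-slope variant can be
assembled from `fitEffect` outputs with `fiellerRatioCI`.

## Meta-analysis

Per-study Cohen's d divides the group mean difference by the pooled SD;
domains scored "lower is better" are sign-flipped first so negative d
always means worse T2DM performance. No small-sample correction by
default (d, not g; Hedges is an option). The sampling variance is the
standard (n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂)). Pooling is random-effects via
`metafor::rma` — REML default, DerSimonian–Laird available; REML is the
modern default of the tooling this mirrors — with normal-based CIs,
Cochran's Q under fixed-effect weights, and I² recomputed as
max(0, (Q−df)/Q)·100 so the identity is exact. Studies contributing
several tests to one domain are averaged within study first (effect =
mean d, variance = mean variance — conservative under positive
correlation of tests); Bonferroni across domains uses the domain count.
Baseline-only extraction from longitudinal studies is a data-preparation
contract on the input table, not code.

## What the synthetic generator emulates

The generator is the package's study population, not a tuning knob; its
defaults are the conditions under which all recovery and calibration
results are stated.

* **Demographics**: integer ages uniform on [50, 80]; half female; 35%
  degree-educated; 35% hypertensive with blood pressure drawn consistently
  with the label; 95% of females menopausal, 5% on hormone therapy; BMI
  ~N(29.5, 4) in diabetics vs N(26.5, 4); head-size factor ~N(1, 0.05).
  The sources behind the motivating analyses publish no covariate
  distributions, so these are pragmatic, field-plausible choices.
* **Disease**: prevalence configurable; true duration gamma(shape 2,
  scale 4.25) — mean 8.5, SD ≈ 6 years — capped at age − 40 and at
  31 years; onset truth = age − duration; three noisy onset reports
  (rounded Gaussian, SD 1 year, truncated at age); among diabetics,
  49% metformin-only and 31% of the remainder on other medication.
* **Volumes**: V = h·[b_r + s_r(age − 50) + D·(k·s_r + e_r) +
  D·α·s_r·duration + ε_r], with baselines from 1,100 mm³ (ventral
  striatum) to 110,000 mm³ (cerebellum), age slopes −0.2 to −1.0% of
  baseline per year (steepest in ventral striatum and Heschl's gyrus),
  T2DM offset scale k = 6 (six years' worth of extra aging, which puts
  the ventral striatum near −6%), acceleration α = 0.26, per-region noise
  SD 3% of baseline (heteroscedastic across regions), intercepts
  referenced to age 50 because the cohort starts there.
* **Overlap truth**: the T2DM offset is k·s + e with e a seeded Gaussian
  draw Gram–Schmidt-orthogonalized against the constant vector and the
  centered slopes, scaled to m·k·‖centered s‖. The population overlap is
  then exactly 1/√(1+m²); the default m = 4/3 plants 0.6. Overlap
  experiments set α = 0 because a duration effect adds α·mean(duration)·s
  to the matched T2DM coefficient, growing the aligned component and
  raising the estimand above 1/√(1+m²) (the worked example shows ≈0.70
  with α = 0.26 for this reason).
* **fMRI**: each voxel carries one sinusoid at a uniform in-band
  frequency with random phase, amplitude 1 scaled by per-cluster,
  per-group multipliers, plus white noise (SD 1). This is deliberately
  minimal: no autocorrelated noise, no motion or physiological artifacts,
  no spatial correlation beyond what smoothing induces.

What passing tests therefore show: the estimators recover exactly the
structure they assume (linear trajectories, additive offsets, Gaussian
noise) at realistic sizes, and their inferential calibration (CI
coverage, FDR control) holds under independence-plus-smoothing. What they
do not show: robustness to nonlinear aging, non-Gaussian or spatially
autocorrelated noise, informative missingness, or self-report biases
beyond symmetric noise. One further artificiality: because the orthogonal
perturbation is scaled by the global slope norm (dominated by the largest
regions), small regions can receive planted offsets that are large in
percent terms; this affects the realism of individual regional
percentages, not the overlap or acceleration estimands.

## Numerical and design choices

* Frequency band edges inclusive; DFT unpadded — reproducible without
  interpolation.
* Missing values are NA throughout, never zero (zero is a valid score).
* Matching treats age as integer years; bins are half-open with origin 0.
* Rank-deficient designs raise an error naming the collinear terms; the
  acceleration fit refuses samples where duration and age are nearly
  collinear (|r| > 0.999) since the joint model cannot separate the
  slopes.
* Degenerate Fieller inputs (all variances zero) return the point ratio
  with a width-zero interval; a zero denominator with zero variance is an
  error.
* Problem sizes used by the acceptance computations: 500 replicate
  cohorts of 4000 diabetic subjects for acceleration recovery; 200 (test)
  / 100 (script) replicates of 2000-subject cohorts for overlap recovery;
  100 null fMRI simulations on 20×20×20×200 grids with 6 subjects per
  arm; 1000 random draws for the Fieller oracle; 100 random instances for
  the matching oracle. These sizes put Monte-Carlo error comfortably
  below the tolerances they are checked against.

## Limitations

Cross-sectional identification; no propensity or caliper matching (exact
strata only — unmatched cases are dropped, so estimates are for the
matched subpopulation); no spatial-autocorrelation-aware p-values for map
overlap (a known optimism when maps are smooth); no fALFF or sub-band
analyses; no registration — images are assumed aligned; the meta-analysis
takes the test-to-domain mapping as input rather than deciding it.
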