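# T2DMAging

Does type 2 diabetes mellitus (T2DM) carve its own degenerative path
through the brain, or does it accelerate ordinary brain aging? `T2DMAging`
implements the full statistical pipeline for answering that question from
cross-sectional cohort data, for epidemiologists and neuroimaging
statisticians: matched case–control construction, per-domain and
per-region effect estimation, resting-state amplitude analysis, effect-map
overlap, an acceleration ratio with an exact Fieller interval, and a
companion random-effects meta-analysis. A synthetic-cohort module plants
known ground truth so every stage is testable without access-controlled
data.

## The statistics at the core

**Matched effect maps.** After eligibility filtering (hypertension labelled
by SBP > 140 or DBP > 90 mmHg; non-menopausal or hormone-treated females
excluded; diabetic subjects with mean self-reported onset < 40 years
excluded), T2DM cases are 1:1 exact-matched to healthy controls (HC) on
integer age, sex, education and hypertension. For each cognitive domain or
each of 45 bilateral gray-matter regions (head-size normalized), an OLS
model

&nbsp;&nbsp;&nbsp;&nbsp;*y = β₀ + β·x + ε*

yields the factor coefficient β with a t-based 95% CI, expressed as a
percentage of the matched-HC mean, Bonferroni-corrected (cognition,
structure) or BH-FDR-corrected (brain activity).

**ALFF.** Voxelwise amplitude of low-frequency fluctuation: linear
detrend, DFT, mean in-band (0.01–0.08 Hz) amplitude √2·|X(f)|/N,
normalized to the subject's in-mask global mean, Gaussian-smoothed
(FWHM 5 mm). Group z-maps are thresholded at FDR q = 0.05 with a
12-voxel minimum cluster extent (6-connectivity).

**Overlap.** The resemblance of the T2DM and age effect topographies is
the Pearson correlation of the two per-region coefficient vectors.

**Acceleration.** Within T2DM subjects, whole-brain gray matter volume is
regressed jointly on age and disease duration (duration = age − mean of
three self-reported onset ages); the acceleration factor is the
coefficient ratio ρ = β_duration / β_age, with its 95% set from Fieller's
theorem — the solution of

&nbsp;&nbsp;&nbsp;&nbsp;(β₂² − t*²v₂₂)ρ² − 2(β₁β₂ − t*²v₁₂)ρ + (β₁² − t*²v₁₁) ≤ 0,

which is a bounded interval exactly when the denominator is significantly
nonzero.

**Meta-analysis.** Per-study Cohen's d (pooled-SD) per cognitive domain,
pooled under a random-effects model (REML default, DerSimonian–Laird
option) with Cochran's Q, I² = max(0, (Q − df)/Q)·100, funnel diagnostics,
and Bonferroni correction across domains.

## Worked example

```r
library(T2DMAging)

co  <- generateCohort(cohortSpec(nSubjects = 2000, t2dmPrevalence = 0.5, seed = 7))
co  <- applyEligibility(co)
attr(co, "exclusions")
#> menopause_or_hormone onset_before_minimum             retained
#>                   93                   23                 1884

mp  <- matchCohort(co[co$t2dm, ], co[!co$t2dm, ],
                   matchSpec(c("age", "sex", "education", "hypertension")))
mp
#> MatchedPairs: 695 pairs, 234 unmatched cases

vols    <- generateRegionVolumes(co, atrophySpec(acceleration = 0.26, seed = 8))
ids     <- c(pairsTable(mp)$case, pairsTable(mp)$control)
t2dmMap <- regionalEffectMap(vols[, ids], "t2dm")
ageMap  <- regionalEffectMap(vols[, co$id[!co$t2dm]], "age")

overlapCorrelation(t2dmMap, ageMap)
#> OverlapResult: r = 0.699, p = 9.06e-08, n = 45

accelerationEstimate(vols)
#> RatioCI: ratio = 0.2539, 95% Fieller set [0.2418, 0.2661] (df = 926)
```

The exclusion log accounts for every subject (93 females failing the
menopause/hormone rule, 23 diabetics with reported onset below 40). The
695 matched pairs give a per-region T2DM atrophy map; its correlation with
the HC aging map (r = 0.70) measures how much the diabetic topography
resembles the aging topography (the generator's default planted overlap is
0.6 before the duration effect, which deepens the T2DM offset along the
aging direction). The acceleration estimate 0.254 [0.242, 0.267] recovers
the planted 0.26: each year of disease adds about a quarter-year of
typical volumetric aging. Slight downward pull reflects the noisy
self-reported onset ages (errors-in-variables attenuation, about 1%).

A YAML-driven runner (`runPipeline()`, or
`Rscript inst/scripts/pipeline.R all --config cfg.yaml --run-dir out`)
chains the stages — simulate, filter, match, effects, overlap, accelerate,
meta, report — writing CSV artifacts, a log and a manifest (config hash,
seed, package version) sufficient to re-run any stage bit-identically.

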