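---
title: "Methods: exposure-wide survival screening with a permutation FDR"
author: "nwascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure-wide survival screening with a permutation FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Nutritional epidemiology screens are plagued by two features that break
one-exposure-at-a-time inference: dietary intakes are strongly
inter-correlated, and dozens of them are tested against the same outcome.
The nutrient-wide association study (NWAS) design answers both in the way
genome-wide studies do: test every exposure agnostically with the same
pre-specified model, correct for multiplicity with an empirically estimated
false discovery rate, and require replication of survivors in an
independent cohort before believing them. `nwascreen` implements that
pipeline for time-to-event outcomes, together with a synthetic cohort
generator so every stage can be exercised and calibrated without access to
restricted cohort data.

## The screening model

Each exposure is tested separately with a stratified Cox proportional
hazards model on the **age time scale**: age at study entry is the
time origin of the underlying process, and a participant contributes to
risk sets only for ages in `(age_entry, age_exit]` (delayed entry / left
truncation). Exit is the age at diagnosis, death, or end of follow-up,
whichever comes first. Baseline hazards are stratified by age band at
recruitment and by recruitment centre, so centre-specific follow-up and
questionnaire differences never enter the likelihood as proportional
effects. The linear predictor holds the exposure plus the confounder set:
total energy (kcal, continuous), smoking status (3 levels), BMI category
(6), physical activity (4), diabetes history (2), education (4), and, in
the replication cohort, family history of the disease (2).

Exposure coding follows standard practice:

* **nutrients** are energy-adjusted by the **residual method** — the
  nutrient is replaced by its residual from a least-squares regression on
  total energy, plus the predicted intake at mean energy so units are
  preserved; the adjusted intake is exactly uncorrelated with energy;
* **foods** are used raw, with energy retained as a model covariate;
* all exposures are then standardized (n−1 denominator), so hazard ratios
  are per 1 SD of intake; quartile coding is available as the sensitivity
  analysis.

Partial-likelihood maximisation, tie handling (Efron by default; ties are
measure-zero on a continuous age scale anyway), Wald inference and the
sandwich variance are delegated to `survival::coxph`; the package's tests
verify the fitted coefficient against a direct brute-force maximisation of
the partial likelihood on small data. Non-convergence and complete
separation are reported through a `converged` flag rather than an
exception, because a screen over ~100 exposures must never abort mid-run.
Strata without events contribute no terms and are dropped with a message.

Proportionality is checked per exposure by the slope of the scaled
Schoenfeld residuals against age (identity transform), the `cox.zph` score
test restricted to the exposure term.

## Permutation-null FDR

The multiplicity correction estimates, for each exposure, the expected
proportion of false positives among results at least as extreme. A null
distribution of p-values is built by **jointly permuting** the pairs
(event indicator, follow-up duration) — along with the subtype labels that
belong to the event — across participants, leaving exposures, confounders,
strata and entry ages in place, and refitting every exposure model on each
of `B` permuted datasets. Joint shuffling preserves the observed outcome
distribution exactly; shuffling status and duration independently is
offered nowhere because it can manufacture impossible records (events
after censoring horizons). The FDR for exposure *i* is the ratio

> (proportion of null p-values ≤ t) / (proportion of observed p-values ≤ t)

capped at 1. Two thresholding modes exist: a fixed threshold t = 0.05 (the
classical ratio at the nominal significance level) and the default
**per-factor** mode t = p&#8321;, which gives each exposure its own FDR. The
per-factor ratios are monotonized step-up style (each exposure receives
the smallest ratio achievable at any threshold ≥ its own p-value), the
same device q-value estimators use; without it a cluster of moderate
p-values can locally invert the ordering. Refits that fail on permuted
data contribute p = 1, which can only push the FDR up, never down.
Benjamini–Hochberg q-values are computed alongside as the standard
sensitivity analysis, and exposures with permutation FDR strictly below 5%
are flagged for replication.

The two modes answer different questions and behave differently under the
global null. The per-factor FDR of the smallest p-value converges to
`m · p_min` — the BH q-value of the minimum — so in about 5% of null
screens *some* exposure carries a per-factor FDR below 5%; that is the
accepted false-discovery tolerance of the quantity, not a defect. The
fixed-threshold ratio, by contrast, compares pooled proportions at the 5%
level, and under the null a selection would need fewer than 3 of
`B · m ≈ 1000` null p-values below 0.05 — practically impossible. The
replication **selection rule** is therefore calibrated (and tested)
against the fixed-threshold definition, while the per-factor mode is the
default for reporting an FDR-adjusted value per dietary factor.

`B = 100` permutations is the default (the calibration tests use 50); the
estimate's granularity is 1/(B·m), which at m ≈ 92 exposures resolves FDR
values well below the 5% decision threshold.

## Replication in a case-cohort design

The replication cohort follows a case-cohort design: a random subcohort
drawn at baseline plus all cases. Fits use **Prentice weighting**:
subcohort members are at risk over their whole follow-up, while cases
outside the subcohort enter the risk set only just before their own event
— operationally, their entry age is set to `age_exit − ε`. The offset is
`ε = 10⁻⁵ × (max exit − min entry)`, a few hours on the age scale: far
smaller than any realistic between-subject gap, yet safely above the
relative tolerance at which `coxph` rounds near-tied survival times (an
offset near double precision would be rounded to a zero-length interval
and rejected). Halving ε does not move the estimate (tested to 1e-8).
Model-based variances are invalid under case-cohort sampling, so these
fits always use the robust (sandwich) variance with participants as
clusters.

## Pooling

Cohort-specific log hazard ratios are pooled by **DerSimonian–Laird
random-effects meta-analysis**: fixed weights `1/se²` give Cochran's Q;
`τ² = max(0, (Q − df)/(Σw − Σw²/Σw))`; random-effects weights
`1/(se² + τ²)`. DL is the standard two-study default in epidemiology; REML
is deliberately not offered because it is unstable with one degree of
freedom. Published results can be pooled directly from HR + CI pairs; the
back-conversion uses the exact normal quantile by default and `z = 1.96`
on request, since published tables are built with 1.96 and carry 2-decimal
rounding — which bounds agreement with published pooled values at ±0.01.

## The synthetic cohort generator

The generator emulates the data structure the analysis assumes, not any
particular real cohort:

* **Exposures** (default 63 foods + 29 nutrients): a latent Gaussian with
  exchangeable within-block correlation (blocks of 4 emulate food groups
  and nutrient families; default within-block correlation 0.4) is
  exponentiated, giving right-skewed, strictly positive FFQ-like
  marginals (log-scale SD 0.25, i.e. CV ≈ 25%) whose rank correlation
  matches the latent target. Real FFQ correlation matrices are not block
  exchangeable; the block design is the simplest structure that makes
  "correlated neighbour of a true signal" a live concern for the screen.
* **Energy**: a positive linear combination of all intakes plus noise
  (mean ≈ 2400 kcal), so energy confounds every exposure by construction;
  an independent energy-requirement column supports ratio trimming.
* **Confounders**: six categorical variables with marginals chosen to
  resemble a middle-aged male European cohort (31% current smokers, 4%
  diabetes, ...), with fixed documented log-HR effects (e.g. current
  smoking 0.20, activity up to −0.10) so confounding is real but known.
* **Events**: a Weibull proportional-hazards model on the age scale,
  shape 6 (incidence rising steeply with age, as for prostate cancer) and
  scale 113.5 years, calibrated so that with entry ages uniform on 45–70
  and a 14-year administrative horizon the cumulative incidence is ≈ 5%.
  Event ages are drawn conditionally on being event-free at entry, which
  is exactly the left-truncation assumption of the analysis model. Centre
  offsets (± 0.15 on the log-hazard) make stratification genuinely
  necessary. The confounder/planted linear predictor is centred at its
  sample mean so the calibration survives parameter changes.
* **Subtype labels** among events follow the marginal frequencies of a
  large published prostate-cancer case series (≈ 39% localized, 19%
  advanced, 41% stage-unknown; 54%/10%/37% low/high/unknown grade; 12%
  fatal); stage, grade and PSA indicators are drawn independently, so the
  derived "aggressive" fraction (advanced OR high grade OR PSA > 20)
  is ≈ 33%, close to but not exactly the ≈ 30% a correlated real series
  shows. Planting subtype-specific effects is done in tests via explicit
  cause-specific competing hazards.
* **Missingness** defaults to 0 — the default cohort emulates the
  post-exclusion analysis set. Setting it positive (≈ 0.022 per
  confounder reproduces a ≈ 12.5% any-missing rate) emulates the
  pre-exclusion roster for exclusion-cascade and missing-indicator work.
* **Reproducibility**: one master seed; every stage (exposures,
  confounders, outcomes, subcohort draw, permutation b) derives a child
  seed through a fixed integer hash (`split_seed`), so changing one stage
  never perturbs another and all artifacts are bitwise reproducible.

What passing tests on this generator do **not** show: robustness to
differential misclassification of diet, to informative censoring, to
screening-driven detection of indolent disease, or to real FFQ
correlation geometry. The generator is a correctness and calibration
harness, not a cohort emulator.

## Numerical and design choices

* Exclusion cascades are applied sequentially in reporting order; a row
  failing several rules is attributed to the first, matching how cohort
  flow diagrams count.
* Energy-ratio trimming uses order-statistic percentiles; a tie group
  straddling the cut is conservatively not flagged, so a degenerate
  constant ratio flags nothing.
* Quartile boundaries go to the lower category; with fewer than four
  distinct values the coding refuses rather than silently collapsing.
* The between-subtype heterogeneity test is an independent-samples Wald
  contrast of two cause-specific log hazard ratios. The two fits share
  person-time, so the independence assumption is approximate and the test
  runs anti-conservative; it is reported as a descriptive diagnostic, not
  a calibrated test.
* The toy partial-likelihood oracle uses an interleaved 6-subject dataset;
  the textbook configuration with all exposed events first is completely
  separated (infinite MLE) and is used instead to test the
  flagged-nonconvergence path.
* Test problem sizes are chosen to make Monte Carlo assertions sharp at
  desk scale: parameter recovery at n = 5000, case-cohort agreement at
  n = 20,000 with a 15% subcohort, FDR calibration on twenty independent
  n = 2000 cohorts with 20 exposures and B = 50 permutations, ranking
  checks at n = 10,000 with 20 exposures over 5 seeds.

## Limitations

Time-varying covariates, frailty terms, competing-risks subdistribution
hazards and penalized Cox are out of scope, as are >2-cohort network
meta-analysis and the Hartung–Knapp adjustment. The pipeline tests the
marginal association of one exposure at a time; it does not attempt to
decorrelate the exposure set, and the FDR is therefore interpreted per
factor against the screen-wide null, in the EWAS tradition.
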