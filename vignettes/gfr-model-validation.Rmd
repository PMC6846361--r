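---
title: "Validating creatinine-based GFR models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating creatinine-based GFR models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfreval)
```

## The problem

Glomerular filtration rate (GFR) drives dose decisions in oncology — most
directly for carboplatin, whose dose is linear in GFR through the Calvert
equation, dose = AUC × (GFR + 25). GFR can be measured (mGFR) by clearance
of an exogenous nuclear tracer (⁵¹Cr-EDTA or ⁹⁹ᵐTc-DTPA), but in routine
care it is estimated (eGFR) from serum creatinine and simple covariates.
Many estimation formulas coexist; they disagree, and their errors
propagate linearly into doses. This package implements eight of the
commonly compared creatinine-based models together with the validation
framework used to rank them against mGFR on multicenter cohorts, and a
synthetic-cohort generator that emulates the structure of such a cohort so
the whole pipeline can be exercised and tested end to end without access
to patient-level data.

## The models

All models take age, sex, serum creatinine (SCr, mg/dL unless noted) and,
where required, weight, height or DuBois body surface area
(BSA = 0.007184 · W^0.425 · H^0.725):

* **Cockcroft–Gault** (absolute mL/min): (140 − age)·W·(0.85 if female)/(72·SCr).
* **Jelliffe** (per 1.73 m²): (98 − 0.8·(age − 20))·(0.9 if female)/SCr.
* **MDRD-186** (per 1.73 m²): 186·SCr^−1.154·age^−0.203·(0.742 if female)·(1.212 if black).
* **CKD-EPI 2009** (per 1.73 m²): 141·min(SCr/κ,1)^α·max(SCr/κ,1)^−1.209·0.993^age·(1.018 if female)·(1.159 if black), κ = 0.7/0.9 and α = −0.329/−0.411 for females/males.
* **Mayo quadratic** (per 1.73 m²): exp(1.911 + 5.249/SCr − 2.114/SCr² − 0.00686·age − 0.205 if female), with SCr below 0.8 mg/dL set to 0.8.
* **Wright** (absolute): (6580 − 38.8·age)·BSA·(1 − 0.168 if female)/SCr[µmol/L].
* **Martin** (absolute): 163·W·(1 − 0.00496·age)·(1 − 0.252 if female)/SCr[µmol/L].
* **CamGFR** (absolute): a square-root-scale linear model,
  √GFR = 1.8140 + 4.7328·BSA − 0.0072·age − 1.0920·ln SCr − 0.6700·SCr.

Coefficients live in a YAML registry
(`system.file("extdata", "model_constants.yaml", package = "gfreval")`),
each set tagged with its source citation and loadable from a user-supplied
path via `gfr_constants()`, so any coefficient can be corrected or swapped
without touching code. Two transcriptions (CamGFR and Martin) are marked
**unverified** in the registry: their primary references print the
coefficients but were transcribed here at second hand, and the registry is
the single place to fix them. Nothing in the validation machinery depends
on any one model's coefficients.

Two unit/scale conventions are enforced centrally: creatinine is converted
to mg/dL on ingest (1 mg/dL = 88.42 µmol/L), and models whose native output
is normalized to 1.73 m² are rescaled by BSA/1.73 before any comparison
with mGFR, because tracer measurements (and the Calvert equation) are
absolute mL/min. Jelliffe's output is treated as normalized by default;
whether a given historical analysis de-normalized it is ambiguous, so its
`native_scale` field in the registry is the switch.

### A numerical corner of the Mayo equation

The Mayo quadratic has a genuine stationary point at
SCr = 2·2.114/5.249 ≈ 0.8055 mg/dL, just above its 0.8 clamp: between 0.80
and 0.8055 the published formula *increases* slightly in creatinine. The
monotonicity audit therefore runs from 0.81 mg/dL upward, and the
assay-bias property (higher creatinine ⇒ lower eGFR) exempts Mayo records
sitting in that sliver. This is a property of the published equation, not
of this implementation; the numeric inversion of Mayo likewise restricts
itself to the strictly decreasing branch above 0.806 mg/dL.

## Cohort rules

`read_cohort()` ingests one row per creatinine–mGFR pair, collecting
malformed rows into a rejects report instead of dropping them.
`apply_inclusion_filters()` retains adults (age ≥ 18) with creatinine in
[0.20, 4.5] mg/dL — both bounds inclusive; "between" is ambiguous in the
source literature, and inclusivity is the documented choice — whose
creatinine was drawn within ±30 days of the mGFR date (the window is
two-sided because no direction is specified). `select_first_mgfr()` keeps
each patient's earliest mGFR, breaking same-date ties by file order
(stable, logged). Every rule appends its exclusion count to a filter log
so cohort accounting can be audited. Quantiles are type 7 (linear
interpolation) everywhere — cohort summaries and residual IQRs alike.

## Performance statistics

For residuals r = mGFR − eGFR (that sign convention throughout):

* **bias** = median(r);
* **precision** = IQR(r) (type-7 quartiles);
* **accuracy** = RMSE = √mean(r²);
* **1-P20** = proportion of patients with absolute percentage error
  |eGFR − mGFR|/mGFR *strictly* greater than 0.20 ("greater than 20%" is
  read strictly; a patient at exactly 20% does not count).

Confidence intervals resample patients with replacement (default 2000
repetitions) and use the normal approximation: estimate ± z·SD of the
bootstrap statistics. Model comparisons are **paired**: both models are
evaluated on the same patients, each bootstrap draw resamples rows once
and recomputes the metric difference for both models jointly, and the
two-sided p-value comes from the normal approximation of the bootstrap
delta distribution. Two-sided is the default (conservative; the
alternative is configurable) and an unpaired comparison is deliberately
not offered, since the design evaluates all models on identical patients.

Subgroup analysis defaults to quartile bins for continuous variables and
categories as-is for discrete ones; bin edges are overridable since
published subgroup analyses often use fixed clinical cut-points. The
matched-draw comparison (used to check for systematic differences between
black and nonblack patients) matches each minority patient 1:1 without
replacement to a majority patient of the same sex within ±2 years of age
(nearest age wins), and compares BSA, mGFR and creatinine with a rank-sum
test by default; the source analyses name neither the tolerance nor the
test, so both are arguments (±2 years and Wilcoxon being conventional
choices for epidemiological matching of this kind).

## The synthetic-cohort generator

The generator emulates the *structure* of a seven-center oncology
validation cohort, not any patient's data:

* **Strata**: per-center totals, diagnosis mix (solid/hematological/
  noncancer), female and black counts follow the published margins
  (total 3786; e.g. Manchester 1777 with 1066 female). The full
  center × diagnosis × sex × race cross-classification is not published,
  so female and black counts are apportioned across diagnoses within each
  center by deterministic largest-remainder allocation. Other cohort
  sizes rescale every cell proportionally.
* **Demographics**: age ~ truncated normal (57, 16) on [18, 91];
  per-sex height and weight truncated normals (175/162 cm and 80/68 kg,
  SD 7 and 17/16) calibrated so the pooled medians are ≈169 cm and
  ≈74 kg at the cohort's 45% female fraction; height and weight share a
  latent size factor giving correlation ≈0.5 (only the marginals are
  published, so the joint is a modeling choice).
* **GFR first, creatinine derived**: a latent true GFR is drawn from a
  truncated normal (86, 32) on [9, 209]; the **truth model** is then
  inverted — analytically for the power-form models, by root-finding for
  Mayo and CamGFR — to find the noiseless creatinine consistent with that
  GFR and the drawn covariates. Generating in this direction guarantees
  the closed-loop identity that anchors the test suite: with zero noise
  the truth model's eGFR equals mGFR exactly, so its RMSE is zero to
  solver precision and any regression in models, units or scale handling
  breaks an exact test.
* **Noise**: measured GFR = true GFR + N(0, 8 mL/min), truncated to
  [9, 209] (≈8 mL/min reflects typical tracer-clearance repeatability of
  5–10%); creatinine is multiplied by lognormal noise (sdlog 0.06, ≈6%
  analytic CV) and by its center's calibration factor (default 1
  everywhere). A record whose final creatinine leaves [0.20, 4.5] mg/dL
  is redrawn (bounded retries), so generated cohorts pass the inclusion
  filters with zero exclusions — mirroring the fact that published
  cohort marginals describe patients *after* inclusion filtering. This
  conditioning slightly trims the GFR tails, which is why the realized
  mGFR standard deviation sits around 30–31 mL/min against a latent 32.
* **Truth model default**: CKD-EPI. It is the best-performing model in
  multicenter comparisons whose coefficients are fully specified in the
  primary literature; CamGFR, the top performer, ships here as an
  unverified transcription and is therefore unsuitable as the default
  data-generating truth. With CKD-EPI as truth and the demographics
  above, the implied cohort median creatinine is ≈0.94 mg/dL, consistent
  with the published joint marginals (median mGFR 85, median creatinine
  0.95).
* **Dates**: mGFR dates are uniform over a four-year study window;
  creatinine is same-day with probability 0.27 (the published same-day
  fraction), otherwise offset uniformly by ±1–30 days.
* **Center calibration**: `inject_center_bias()` multiplies one or more
  centers' creatinine by a factor, emulating intercenter non-IDMS assay
  variability; because all models decrease in creatinine, a factor above
  1 depresses eGFR and degrades accuracy at that center.

What the generator does **not** emulate: the right-skew of real age and
weight distributions (its truncated normals are symmetric, so the
generated age *median* is ≈57 rather than the published 60 even though
the mean matches), any real center-specific creatinine distributions,
correlation between creatinine and mGFR measurement errors (assumed
independent), or longitudinal treatment effects. Tests passing on
generated cohorts therefore demonstrate the correctness of the
statistical machinery and formula implementations under a controlled
truth — not the clinical ranking of models on real patients.

## Randomness and determinism

Every stochastic entry point takes a seed; a single root seed is
hierarchically derived into independent streams per operation (generator,
per-model bootstrap, per-draw matching), recorded in reports and run
manifests, and reproduces outputs bit-for-bit. Bootstrap intervals use
2000 repetitions by default. The test suite's coverage check (nominal 95%
intervals covering a known true RMSE in 92–98% of simulations) runs 200
simulations of n = 500 with 500 repetitions per interval — repetitions
only stabilize the bootstrap SE estimate, not the interval's coverage,
and 500 keeps the check cheap; rank-recovery runs ten seeded cohorts of
n = 2000; marginal calibration checks average ten full-size cohorts.

## Known limitations

* CamGFR and Martin coefficients are unverified transcriptions (flagged
  in the registry); correct them from the primary sources before any
  clinical use.
* The generator is calibrated to one cohort's printed margins; it is not
  a general patient simulator.
* Bootstrap intervals use the normal approximation by design fidelity;
  for strongly skewed metrics at small n, percentile intervals (not
  offered) would differ.
* eGFR is not capped for dosing; the Calvert helper applies no clinical
  guardrails beyond input validation.
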