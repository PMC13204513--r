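---
title: "External validation of neonatal vancomycin popPK models with neovanc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{External validation of neonatal vancomycin popPK models with neovanc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovanc)
```

## The problem

Vancomycin dosing in neonates is difficult: renal elimination matures
rapidly with postmenstrual age (PMA), body size spans an order of
magnitude, and serum creatinine (SCr) varies with both maturation and
illness.  Population pharmacokinetic (popPK) models promise
model-informed precision dosing, but a model fitted in one unit can carry
site-specific artifacts, so before clinical use it must be validated
externally: its *a-priori* predictions (from covariates and dosing history
alone, with no conditioning on the patient's measured levels) are compared
against independently observed therapeutic-drug-monitoring (TDM) troughs.

`neovanc` implements that validation pipeline end to end: a declarative
model registry with the Chung 2023 neonatal vancomycin model built in, a
closed-form intermittent-infusion prediction engine, the standard
prediction-error metric set with bootstrap confidence intervals and
predefined acceptance criteria, visual predictive checks (VPC),
trough-stratified clinical-outcome and acute-kidney-injury (AKI)
analyses, and a seeded synthetic-cohort generator so every stage is
testable without patient data.

## The built-in model

The Chung 2023 one-compartment model expresses typical clearance and
volume as

$$CL = 13.9 \cdot \frac{WT}{70} \cdot
  \frac{PMA^{0.739}}{PMA^{0.739} + 47.7^{0.739}} \cdot
  \left(\frac{SCr}{34}\right)^{-0.653} \quad \text{(L/h)},
\qquad
V = 65.5 \cdot \frac{WT}{70} \quad \text{(L)},$$

with weight in kg, PMA in weeks and SCr in µmol/L.  The three factors are
the field's standard covariate-model building blocks: linear (here) or
allometric weight scaling to a 70 kg reference, a Hill (sigmoid-Emax)
maturation function of PMA with half-maximal maturation at 47.7 weeks, and
a power function of SCr referenced to 34 µmol/L capturing renal function.
The registry (`poppk_model()`) declares models as products of exactly
these term kinds — `power`, `hill`, `linear` — over a fixed covariate
vocabulary, which is expressive enough for the published neonatal
vancomycin models without admitting a free-text formula interpreter.

```{r}
cov <- covariate_set(weight_kg = 1.06, pma_weeks = 28.9, scr_umol_L = 56)
params <- evaluate_model(chung2023_model(), cov)
params
half_life(params)
```

At the cohort-mean covariates of a very-preterm NICU population the model
gives CL ≈ 0.062 L/h and V ≈ 0.99 L, i.e. a half-life of about 11 h —
why troughs are drawn before the 4th dose, when most (not all) neonates
approach steady state.

The inter-individual-variability (IIV) and residual-error slots of the
shipped definition deserve a caveat: the published typical-value
equations do not fix them, so `chung2023_model()` defaults to lognormal
variances of 0.1 on CL and V and an additive residual SD of 2 mg/L.
These defaults only matter for simulation-based use (VPC, synthetic
cohorts); point prediction uses typical values alone.  Both slots are
arguments, so users with the original estimates can supply them.

## Predicting concentrations

Doses are modelled as 1 h zero-order infusions (the institutional
protocol; the duration is per-dose configurable) with first-order
elimination, evaluated by closed-form superposition (the Sawchuk–Zaske
short-infusion model) in `concentration_at()`.  Infusion intervals are
half-open `[start, start + Tinf)`, and the test suite checks the engine
against an independent ODE integration to ≤ 1e-6 relative error.

`predict_for_observations()` implements the a-priori prediction rule:
for each sampling time, covariates are taken from the most recent record
at or before that time (last observation carried forward — the
conservative EHR convention; how mid-course SCr changes should be handled
is genuinely open, and carry-forward is this package's documented choice),
parameters are evaluated, and the superposition sum is taken over the
reconstructed dosing history.

## Validation metrics and criteria

With prediction error $PE_i = C_{pred,i} - C_{obs,i}$, `compute_metrics()`
reports ME (mean PE, bias in mg/L), RMSE, relative mean and median PE
(mean/median of $PE_i / C_{obs,i}$, in %), and p30 (the percentage of
predictions within 30% of the observed value, boundary inclusive).  The
relative metrics are defined per-observation because p30 is explicitly
per-observation-relative and mixing conventions would make the five
metrics incommensurable.  Observations below the 4 mg/L quantification
limit are replaced by 2 mg/L and flagged (`preprocess_blq()`); they enter
the metrics by default, with exclusion available by filtering on the
`bql` flag.

`bootstrap_ci()` gives percentile 95% intervals over 1000 nonparametric
resamples, at the observation level by default; a patient-level
(cluster) option is behind the `cluster` argument because trough-only
designs have few observations per patient and either convention is
defensible.

`apply_criteria()` encodes the predefined acceptance thresholds —
|ME| ≤ 0.5 mg/L, |Rel ME| ≤ 15%, |Rel MdE| ≤ 15%, RMSE < 10 mg/L,
p30 > 45% — read exactly as printed: the "within ±" bounds inclusive, the
inequalities strict.  Five criteria met classifies a model highly
predictive, three or four moderately predictive.  `rank_models()` orders
models by criteria met, breaking ties by lower RMSE and then lower |ME|;
the tie-break is this package's convention, since criteria counts alone
leave ties.

```{r}
tab <- read.csv(system.file("extdata", "published_validation_metrics.csv",
                            package = "neovanc"), check.names = FALSE)
rank_models(tab)[, c("model", "rmse_mg_L", "n_met", "classification")]
```

`subgroup_residuals()` summarises residuals across the standard neonatal
development strata (PNA ≤7/>7 days; five PMA tiers from extremely preterm
to term; weight </≥1.5 kg; SCr </≥90 µmol/L) with Mann–Whitney or
Kruskal–Wallis tests as appropriate.

## Visual predictive check

`simulate_replicates()` simulates the model on the cohort's *actual*
design — real dosing records and sampling times — drawing IIV per patient
and residual error per observation, and censoring simulated values with
the same BLQ rule as the data so the two distributions stay comparable.
`vpc_summary()` bins by time, overlays observed percentiles on the
simulated 5/50/95 bands (the levels and the quantile-spaced binning are
package defaults, reported in the output, since no single convention is
canonical), and reports the share of observations inside the outer band.

## Outcomes and AKI

`classify_trough_band()` bands initial troughs against the 10–15 mg/L
neonatal target, boundaries inclusive in the target band.
`assess_aki()` implements the modified neonatal RIFLE screen: AKI at an
on-therapy SCr rise ≥50% over baseline, an absolute rise ≥27 µmol/L, or
any urine-output interval <1 mL/kg/h, with baseline the last SCr at or
before the first dose and a urine-only fallback when baseline SCr is
missing.  Stages above 1 use the conventional 1.5×/2×/3× ratio cutoffs,
labelled as convention since only the stage-1 definition is guaranteed.
`stratified_outcome_table()`, `fisher_exact_rxc()` and
`target_attainment()` reproduce the band × outcome contingency analyses
(default restricted to courses ≥5 days).

## The synthetic cohort

`cohort_spec()` fixes the study conditions the generator emulates:

* covariate marginals of a very-preterm cohort — GA truncated normal
  26.4 (3.22) weeks on [22, 34], PNA lognormal with median 12 days and
  IQR 8–21 truncated to [1, 27] days, SCr lognormal with median
  56 µmol/L and IQR 39–79.5, urine output truncated normal
  3.89 (1.56) mL/kg/h;
* weight linked to GA by a lognormal regression (slope 0.13 per log-kg
  per week, residual SD 0.18 on the log scale) because only marginal
  summaries are published; the truncated-normal location and the link
  intercept are solved analytically so the declared means are the
  realized means;
* the dosing protocol — 10 mg/kg per dose, q12h below 30 weeks PMA and
  q8h at or above, 1 h infusions, course durations 5–14 days;
* trough sampling 30 minutes before the 4th dose (the pre-dose offset is
  unstated in practice; 30 min is a typical charting gap), optionally
  repeated before every 6th subsequent dose;
* the truth model (default `chung2023_model()`) with its IIV and
  residual error, and the 4 → 2 mg/L BLQ rule.

`generate_cohort()` retains the noiseless concentrations and individual
parameters in a separate `truth` element, which is what makes closure
tests possible: validating the truth model against its own data with
IIV = 0 and additive error σ must give ME → 0 and RMSE → σ, and passing
all five criteria; inflating clearance by 1.5× must under-predict (PE
negative) and fail the bias criterion.  `inject_aki()` adds
exposure-dependent SCr/urine trajectories whose selection probability is
set per trough band, so the AKI classifier can be validated against a
known ground truth; unselected courses are constructed to stay strictly
below every threshold.

What the generator does *not* emulate: real joint covariate dependence
beyond the GA–weight link (e.g. SCr is drawn independently of GA),
time-varying covariates within a course, dose adjustments after TDM,
irregular dosing, and assay-specific error structure.  Passing closure
tests therefore demonstrates the internal consistency of the pipeline,
not the field performance of any model on real neonates.

## Numerical and design notes

* Boundary conventions: BLQ is strict (`< 4`), p30 inclusive (`≤ 30%`),
  criteria as printed, target band inclusive at 10 and 15 mg/L.
* The prediction engine refuses two-compartment parameter sets rather
  than silently mis-evaluating; the registry can express them, but no
  closed-form evaluator ships because trough-only data cannot inform the
  distribution phase.
* All stochastic entry points (`generate_cohort()`, `bootstrap_ci()`,
  `simulate_replicates()`, `sample_individual_params()`,
  `run_pipeline()`) take a `seed` and run under a private RNG state, so
  results are reproducible and the session RNG is never disturbed.
* Exact rank tests are used for small untied samples, with the
  normal/chi-square tie-corrected approximations above that; the method
  actually used is reported.
* Problem sizes in the test suite (e.g. 500 patients × 4 troughs for the
  closure property, 400 VPC replicates, 500 bootstrap meta-replicates)
  were chosen as the smallest sizes at which the targeted tolerances are
  statistically meaningful.

## Limitations

The package validates models; it does not fit them (no nonlinear
mixed-effects estimation), and it ships only the Chung 2023 definition —
other published models are expressed by users through the registry
schema.  Adjusted (confounder-controlled) outcome models are out of
scope: only raw contingency analyses are produced.  Trough-only designs
preclude AUC-based exposure metrics by construction.
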