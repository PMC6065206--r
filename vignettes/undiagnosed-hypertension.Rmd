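---
title: "Detecting undiagnosed hypertension: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting undiagnosed hypertension: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htngap)
```

## The estimand

For a population of adult patients with at least one ambulatory
evaluation-and-management visit in a calendar year, we want the difference
between the hypertension prevalence the population *should* exhibit given
its composition, and the prevalence actually *documented* in the
organization's data. The difference, in percentage points, multiplied by
the population size, estimates the number of patients whose hypertension is
potentially undiagnosed.

Both sides of the comparison are defined on the same denominator: patients
aged 18–85 at the start of the observation year with an in-year ambulatory
E&M encounter (`eligible_patients()`).

## Observed prevalence: nested case definitions

Observed prevalence is computed under three nested definitions
(`hypertension_tier()`), each admitting strictly more evidence:

1. **Claims** — any in-year billing claim with a hypertension ICD-10-CM
   code. Matching is by code prefix on the undotted string (`I11` matches
   `I11.9`); the default prefix set {I10, I11, I12, I13, I15, I16} follows
   common claims-algorithm practice and is fully configurable through
   `code_sets()`, since organizations differ in which codes they treat as
   authoritative.
2. **Claims or problem list** — adds patients whose EHR problem list
   carries a hypertension code but who were never billed for it.
3. **Plus BP criteria** — adds patients meeting neither definition whose
   in-office readings are elevated: one reading ≥ 160/100 mm Hg, or
   readings on two *different calendar days* each ≥ 140/90 mm Hg
   (`bp_criteria_met()`). Two elevated readings on the same day never
   qualify. A threshold is crossed when either the systolic or the
   diastolic component crosses it; requiring both is available as
   `bp_rule = "and"` for sensitivity analysis, because the staging
   shorthand "≥ 140/90" is ambiguous on this point. Patients in this tier
   are flagged for reassessment, not counted as diagnosed — office readings
   taken under routine conditions can overstate BP, and a fraction of these
   patients will not have hypertension on standardized measurement.

Each patient receives exactly one tier, the first whose criterion is met in
the order claims → problem list → BP. By construction the three observed
prevalences are non-decreasing; the test suite asserts this as a property
on randomized cohorts rather than as any particular value.

Comorbidities (obesity, diabetes, chronic kidney disease) are ascertained
from the same three sources (`condition_flags()`). The clinical criteria
and their rationale:

* obesity — any BMI ≥ 30 kg/m² (a single measurement defines the category);
* diabetes — any HbA1c ≥ 6.5 %, or fasting glucose ≥ 126 mg/dL on two
  distinct dates (a single elevated glucose is not diagnostic, mirroring
  standard confirmation practice; HbA1c needs no repeat);
* CKD — eGFR < 60 mL/min/1.73 m² twice, at least 90 days apart (the
  chronicity requirement; a single low eGFR may be acute).

All cutoffs live in `code_sets()` (units: kg/m², %, mg/dL,
mL/min/1.73 m², days), not in code.

## Predicted prevalence: indirect standardization

`predicted_prevalence()` applies a reference table of stratum-specific
prevalences π~s~ (with standard errors) to the analyzed population's
stratum weights w~s~:

$$\hat{p} = \sum_s w_s \pi_s, \qquad
  \mathrm{se}(\hat{p}) = \sqrt{\sum_s w_s^2\, \mathrm{se}_s^2},$$

with a 95 % Wald interval clipped to [0, 1]. The estimate is a convex
combination, so it always lies between the smallest and largest reference
stratum prevalence, and a population whose composition equals the
reference population's own returns the reference overall prevalence; both
properties are tested to 10⁻¹².

Strata are sex × race/ethnicity × age group (18–44, 45–64, 65–74, 75–85),
optionally × comorbidity-count bucket (0, 1, 2–3 of obesity, diabetes,
CKD, ascertained at a chosen evidence level). Two modes are supported
because the analysis can be run with or without organization-specific
comorbidity information:

* **org-specific** — joint weights computed patient by patient
  (`stratum_weights(use_comorbidity = TRUE)`) against the joint-mode table;
* **reference** — demographic-only weights against the table folded over
  the reference population's own bucket distribution,
  $\pi_{demo} = \sum_b q_{b|demo}\, \pi_{demo,b}$
  (`fold_reference_comorbidity()`), with SEs folded in quadrature by the
  same weights.

`tool_compatibility_weights()` additionally emulates a summary-level
interface: joint weights as the product of a demographic marginal and a
bucket marginal under independence. Whether a published calculator
multiplies marginals or uses the joint table internally is generally not
observable from outside, so both routes exist and a numerical identity test
checks that folding-then-predicting equals predicting with
reference-bucket product weights.

### Design choices that were genuinely open

* **CI for the predicted prevalence.** No single convention exists;
  the default propagates the reference table's stratum SEs (above), which
  treats the analyzed population's composition as fixed and the reference
  prevalences as estimated. A Wald interval on the organization's n
  (`ci_method = "wald"`) is available. Published intervals computed under
  an unknown method are therefore not treated as exactly reproducible.
* **Missing race/ethnicity.** Reference tables do not carry a "missing"
  stratum. Patients with missing race/ethnicity are redistributed
  proportionally over the known race categories *within their cell* (sex ×
  age group, plus bucket in joint mode), which keeps weights normalized
  without inventing a reference stratum and preserves within-cell
  known-race proportions exactly (tested by brute-force reallocation). A
  cell containing only missing-race patients falls back to the cohort-wide
  known-race marginal.
* **Observed prevalence is a census.** The difference CI in
  `gap_compare()` shifts only the predicted CI by the observed value;
  the observed prevalence is a complete count over the denominator, not a
  sample estimate.
* **Display rounding.** Prevalences and differences to one decimal,
  additional-patient counts to the nearest thousand, cohort totals to
  two-decimal millions — the granularity at which such results are usually
  reported. Unrounded values are always retained in the returned objects
  (`additional_patients_raw`).
* **One-in-N.** `round(predicted_pct / diff_pp)` with base R's rounding;
  undefined (NA, never a number) when the gap is not positive.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage has testable ground truth.
What it emulates:

* **Demographics** follow a configurable mix; the default is a large 2016
  US multispecialty population: 57.3 % female; 34.2/39.5/16.9/9.4 % across
  the four age bands; 73.9 % non-Hispanic white, 7.1 % non-Hispanic Black,
  3.4 % Hispanic, 10.5 % other, 5.1 % missing; 25 organizations. The three
  dimensions are sampled independently (a simplification — real
  populations have age-by-race structure).
* **True hypertension** per stratum: the default surface
  (`default_htn_prevalence()`) rises steeply with age and implies an
  overall true prevalence near 39 %. Within a stratum, prevalence is
  tilted by the true comorbidity-count bucket with relative risks
  (1, 1.6, 2.4 by default), rescaled so the stratum marginal is preserved
  exactly — this makes the comorbidity dimension informative without
  distorting the demographic surface, and is shrunk per stratum whenever a
  tilted probability would leave (0.005, 0.995).
* **Documentation** is deliberately incomplete: a true hypertensive is
  billed with probability 0.75 (default), otherwise problem-listed with
  probability 0.10, otherwise visible only through BP readings. These
  defaults make the simulated claims/problem-list/all-data observed
  prevalences echo the familiar pattern of documented prevalence rising as
  data sources are added. Comorbidity sensitivities are likewise
  source-graded (e.g. obesity is billed for only 24 % of true cases but
  has a BMI on record for 97 %, so clinical data dominate its
  ascertainment). Per-organization log-normal tilts (SD 0.15) on all
  documentation sensitivities create cross-organization spread.
* **BP readings**: one per visit, mean 150/92 mm Hg for untreated true
  hypertensives vs 118/74 otherwise, visit-level noise SD 12/8. The noise
  is wide enough that some normotensives cross the office thresholds —
  exercising the caveat that BP-criteria patients may not have
  hypertension on reassessment. 5.9 % of patients (default) have no BP
  reading at all.
* **Reproducibility**: every patient draws from a substream keyed by
  (seed, patient index), so enlarging a cohort never changes the patients
  already generated; this is asserted in the tests.

`generate_reference_table()` returns the truth implied by the parameters —
joint-mode bucket-conditional prevalences that fold back to the marginal
surface exactly — with standard errors from a pseudo-survey of
configurable size per stratum (`se = sqrt(p(1-p)/n)`). It is clearly a
synthetic stand-in: no national-survey values are shipped or fabricated,
and users supply their own reference table for real analyses
(`read_reference_table()`).

What the generator does **not** emulate: treatment and BP control among
diagnosed hypertensives (true hypertensives always have elevated BP
means, so the BP tier is more sensitive here than in reality, where
controlled patients read normal); disease progression, mortality,
seasonality; correlation of comorbidities with each other or with
demographics beyond the bucket tilt; coding errors and false-positive
claims (available via `claims_false_positive_rate`, default 0). Passing
tests on synthetic data therefore validate the *mechanics* of
ascertainment and standardization, not the clinical accuracy of any
particular code list on real data.

## Numerical and degenerate-input conventions

* Dates are ISO-8601 calendar dates; all comparisons are whole-day.
* An empty reading list fails the BP criterion; an empty eligible set is
  an error everywhere a denominator is needed.
* Weights must sum to 1 within 10⁻⁹; reference tables must contain every
  stratum (missing strata are an error naming the first offender, never
  silently imputed).
* Organizations with zero eligible patients are excluded from per-org
  reports with a warning.
* Negative gaps (observed above predicted) are reported with their sign,
  never truncated.

## Problem sizes used in the test suite

Monte-Carlo checks use cohorts of 10,000–50,000 patients with tolerances
set at 3 binomial standard errors of the target quantity; property-based
checks run on thousands of randomized mini-cohorts (40–200 patients)
against independent brute-force oracles. The parameter-recovery check
simulates 50,000 patients with uniform 35 % true prevalence and 85 %
claims sensitivity, and verifies observed ≈ 29.75 %, predicted ≈ 35 % and
a gap of ≈ 5.25 points, each within 3 Monte-Carlo SEs — the
documentation-sensitivity identity `gap ≈ (1 − s) · p` that makes the
pipeline's "undiagnosed" estimate interpretable.

## Known limitations

* Ascertainment is diagnosis-code- and measurement-based only; medication
  history (antihypertensive prescriptions) is not used.
* The default code lists are starting points, not validated phenotypes;
  real deployments should review them against local coding practice.
* Indirect standardization inherits the reference table's population: if
  the reference survey's measurement protocol differs from office practice
  (it usually does), part of any gap reflects measurement setting rather
  than missed diagnoses.
* Age is taken as of January 1 of the observation year and stored
  directly; analyses that define age at visit will differ at band
  boundaries.
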