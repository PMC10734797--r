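---
title: "Methods: a claims-based proxy EDSS for multiple sclerosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a claims-based proxy EDSS for multiple sclerosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedss)
```

## The estimation problem

The Expanded Disability Status Scale (EDSS) is the standard clinician-rated
disability measure in multiple sclerosis: an ordinal scale from 0.0 (normal
examination) to 10.0 (death from MS) in half-point steps, built from seven
functional-system scores and an ambulation assessment. Administrative claims
record none of this directly, but they do record its downstream traces:
symptom diagnoses (ICD-10-GM in German claims), symptomatic drug
prescriptions (ATC), and billed medical aids (Hilfsmittel codes). The proxy
EDSS (pEDSS) maps those traces to an integer disability step 0–9 through a
deterministic rule cascade. This vignette documents the model, its tunable
parameters, the numerical conventions, and what the synthetic-data-based
tests do and do not demonstrate.

## The rule cascade

All evidence is collected in an assessment window around an index date
(default ±90 days, both ends inclusive). "Three months" is deliberately
implemented as 90 fixed days: month arithmetic is ambiguous around month
ends, fixed-day windows are reproducible, and the half-width is a parameter
(`days_before`, `days_after`) for sites that prefer calendar months.

Evidence enters the profile under three rules:

* **Qualified diagnosis.** A symptom's diagnosis evidence counts only with
  ≥1 inpatient diagnosis or ≥2 *confirmed* outpatient diagnoses on at least
  two distinct service dates. Distinct dates is the weakest defensible
  reading of "two confirmed outpatient diagnoses"; a stricter
  distinct-calendar-quarters variant (the M2Q convention of German claims
  research) is available as `require_distinct_quarters = TRUE`.
* **Medication/therapy counts.** Prescriptions need no confirmation
  qualifier (they are dispensing records); we count *distinct* drug or
  therapy codes per severity tier, so refills do not inflate severity.
* **Highest tier wins.** A symptom qualifying at several severity tiers is
  counted once, at its highest tier, so one clinical problem cannot be
  double-counted across tiers. Severity escalation by treatment (spasticity:
  descriptor alone = mild, + baclofen = moderate, + intrathecal pump =
  severe) is encoded as separate catalog rows per evidence kind rather than
  a runtime escalation rule, which keeps the cascade a pure function of
  counted evidence.

The cascade itself is evaluated top-down (step 9 first) and returns the
highest satisfied step; `compute_pedss()` also reports the clause that
fired, which makes individual scores auditable. Two readings fixed here:
step 3's "≤2 moderate symptoms" means 1–2 (0 falls through), and ≥4
moderate symptoms resolves to step 5 before step 4's "3 moderate symptoms"
is ever tested — that precedence is what makes the printed step definitions
mutually exclusive. Step 2 accepts only diagnosis evidence, as defined; two
mild-tier drugs without any diagnosis remain step 1 (`mild_drug_count ≥ 1`).
Step 5's "≥4 moderate" counts diagnoses only, not drugs. `alive_at_period_end`
is an input derived from the death table against the study end, never
inferred from claims; a bed-confinement profile for a patient who died
before period end falls through to step 8 at most.

The engine produces step 0; the 0→1 imputation (`impute_pedss()`) belongs
to the validation pathway only, because specialist-center validation
cohorts contain no EDSS 0.0.

## The symptom catalog

The code→symptom→severity dictionary is a first-class input
(`symptom_catalog()`, YAML serialization via `read_catalog()` /
`write_catalog()`), because the full adjudicated symptom list is
site-specific. The shipped `default_catalog()` contains (a) every code with
a fixed, published role in the cascade — fampridine N07XX07, gait
disturbance R26.0/.1/.2/.8, paraplegia G82.12/G82.22/G82.63/M62.3,
tetraplegia G82.42/G82.52, bed confinement R26.3, and the aid stems
10.50.01 (walking stick), 18.50/18.51 (wheelchair), 19.40.01 (chair/bed) —
and (b) a demonstration set of symptom entries spanning all tiers and
evidence kinds, including the visual/brainstem exemplars H49, H51, H53.278
and H55. The tiers of set (b) are plausible placeholders, labeled as such:
do not interpret severity output on real data without a clinically
adjudicated catalog. ICD and aid codes match by prefix at the granularity
stored (entry `H55` matches `H55.0`; stem `18.50` matches product
`18.50.04`), ATC entries match exactly.

## Rescaling, classifiers and metrics

Reference EDSS scores are rescaled by flooring half points (1.0–7.5) and
grouping 8.0–9.5 as "8plus" (these steps all describe patients without
ambulation). Three groupings are evaluated: eight-fold (steps 1–7, 8plus),
three-fold (1–3 / 4–5 / ≥6) and binary (<6 / ≥6) — the ≥6 boundary is the
clinically salient transition to assisted ambulation. A proxy step of 9
enters the top group of every scheme.

Per class we build the one-vs-rest 2×2 table and report sensitivity,
specificity, PPV, NPV, accuracy, Cohen's κ of that 2×2 table, and F1;
overall performance is the macro-averaged F1 over *unrounded* per-class F1
values, and MSE/MAE are computed on the numeric step encoding with "8plus"
as 8 (its lower bound, consistent with flooring) regardless of scheme.
Conventions for degenerate tables: proportions with zero denominators are
0, F1 is 0 when precision + recall is 0, κ is 0 when chance agreement is 1.
Every label of a scheme gets a row even when absent from the data (its F1
is then 0), which keeps macro F1 comparable across runs. The per-class κ
confidence interval is not implemented: no estimator reproduces a published
interval unambiguously, and the point estimate is what the one-vs-rest
table determines.

`validation_counts()` ships the published validation study's one-vs-rest
confusion counts (100 paired index measurements, 13 class rows); pushing
them through `class_metrics()` and `macro_f1()` reproduces the published
per-class metrics and the macro F1 of 0.25 / 0.68 / 0.84 for the
eight-fold / three-fold / binary schemes, and a binary κ of 0.687 — these
are recomputed, not stored. One printed cell (specificity of the step-5
row, 0.87 where its own counts give 83/96 = 0.86) is internally
inconsistent in the source table; the counts are taken as authoritative.

## The synthetic-claims generator

`generate_cohort()` emulates the validation setting, not German claims at
large. Each patient draws a latent step from a bimodal distribution with
modes at steps 1–3 and 6–7 (the shape repeatedly described for MS
populations) and 1–18 reference measurements with mean ≈ 6.2 (a shifted,
truncated Poisson). For every measurement the canonical minimal claims
evidence of the step is emitted — confirmed outpatient pairs on distinct
dates for qualified diagnoses, single events for aids and fampridine — and
then degraded:

* diagnosis capture by tier: mild 0.25, moderate 0.45, severe 0.85 —
  qualitative anchors only (mild/moderate symptoms are poorly documented in
  claims; severe ones reliably);
* aid capture: walking stick 0.22, wheelchair 0.86, chair/bed 0.85 — the
  first two anchored to the observed validation shares of documented
  walking sticks (2/9) and wheelchairs (6/7), the third set equal to the
  wheelchair rate as both are reimbursement-critical;
* outpatient qualifier: confirmed with probability 0.9, otherwise
  suspected (which disqualifies a pair);
* drug emission 0.20/0.35/0.60 by tier, also used for fampridine and (on
  the diagnosis side) bed confinement at the severe tier — plausible
  tunable values, not published facts;
* uniform date jitter of ±30 days, clamped to the window.

One latent step per patient (no within-patient progression), no deaths by
default, full coverage intervals. All randomness flows from a single seed;
the caller's RNG state is untouched.

What passing tests show: the cascade is an exact inverse of the canonical
evidence (100% step recovery at full capture, ≥500 measurements), the
implementation equals an independent max-of-satisfied-steps oracle on all
13,824,000 enumerable profiles, degrading mild/moderate capture increases
under-prediction, and broad severity groupings outperform step-level
prediction under realistic capture. What they do not show: performance on
real claims, where coding practice, comorbidity noise, miscoding and
informative missingness are richer than independent per-unit thinning, and
where the true symptom dictionary matters. The simulated eight-fold macro
F1 under default capture (≈0.6) is accordingly better than the published
real-data value (0.25) — the generator under-models mild-symptom noise by
design, and only the *ordering* of classifier performance is treated as a
testable property.

## Cohort selection

`select_cohort()` implements the population-level filters for applying the
proxy to a whole insurance fund: the MS case rule (≥1 inpatient or ≥2
confirmed outpatient G35 diagnoses inside an inclusion period), index at
the first qualifying MS diagnosis, adults only (age from birth year — claims
carry no birth date), continuous insurance from 12 months before index
through study end (a coverage end explained by death is tolerated there and
handled by the vital-status filter), exclusion of pregnancy-related and
other demyelinating-disease diagnoses in the same window, and survival
through the 12-month follow-up. The exclusion code lists are configuration
(defaults: ICD chapter O plus Z34/Z35; G36/G37) because no authoritative
list is published. Attrition is reported per filter, in order.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data:
the exhaustive cascade check enumerates all 2^9 flag combinations × symptom
counts 0–5 per tier × drug counts 0–4 per tier in vectorized chunks (13.8M
profiles, a few seconds); round-trip and degradation checks use 90–150
patients (≈500–1000 measurements), sizes at which the stochastic ordering
properties are stable across seeds while the whole suite stays fast. Dates
are ISO-8601 throughout; intervals are closed on both ends; coverage
intervals are merged when overlapping or adjacent (1-day gap) before the
continuity check; ties in code matching are broken by longest (most
specific) stored code first, then lexicographically.

## Known limitations

* The proxy is designed for living patients; step 10 (death from MS) is out
  of scope by construction.
* Mild disability is structurally under-identified in claims; step-level
  prediction below 6 should not be trusted on real data.
* The shipped catalog's non-special severity tiers are placeholders; results
  on real data are only as good as the supplied catalog.
* MS subtype, relapses, and functional-system sub-scores are not estimated.
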