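---
title: "Reporting-odds-ratio signal detection: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporting-odds-ratio signal detection: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorscreen)
```

## The model

Spontaneous reporting systems record *reports*, not patients at risk, so no
incidence can be estimated. Disproportionality analysis instead asks whether
an adverse event is over-represented among reports that mention a drug. For
a stratum of deduplicated, eligible reports, cross-classify each report by
drug exposure and outcome-event membership:

|            | event  | no event |
|------------|--------|----------|
| drug       | $n_{11}$ | $n_{12}$ |
| all others | $n_{21}$ | $n_{22}$ |

The reporting odds ratio and its Wald 95% interval are

$$ROR = \frac{n_{11}/n_{21}}{n_{12}/n_{22}}, \qquad
CI = \exp\left\{\ln ROR \pm 1.96\sqrt{\tfrac{1}{n_{11}}+\tfrac{1}{n_{12}}+\tfrac{1}{n_{21}}+\tfrac{1}{n_{22}}}\right\}$$

with the natural logarithm and $z$ fixed at exactly 1.96. A *signal* is a
lower bound strictly above 1. The ROR indicates reporting disproportion,
never risk or causation: reporting rates are shaped by notoriety bias,
under-reporting, and channeling, which no amount of arithmetic removes. The
companion two-sided Fisher exact p-value uses the point-probability
definition (sum of all hypergeometric outcomes no more probable than the
observed table, both margins fixed).

Assumptions worth making explicit:

* **One unit per case.** Counting is case-level: a report listing three
  matching preferred terms contributes one unit to one cell. Cells then sum
  to the stratum's report count.
* **Comparator.** The reference group is *all other reports* in the same
  source and stratum — including reports of same-class drugs. That matches
  how surveillance tables are conventionally built; `exclude_class = TRUE`
  removes all screened drugs from the comparator for sensitivity analysis.
  The point estimate is invariant to comparator size (only the CI narrows),
  which the test suite checks explicitly.
* **Zero cells.** The estimator is undefined when any cell is zero; results
  carry `NA` with a `zero_cell` reason rather than 0 or infinity. The
  optional Haldane +0.5 correction is off by default because the reference
  presentation prints "-" for such rows.
* **No multiplicity adjustment.** Screens are hypothesis-generating;
  unadjusted signals are reported, as is field convention.

## Preprocessing rules

* **Deduplication** keeps the report with the maximal version key per case
  (FAERS recommends analysing only the latest case version), breaking ties
  deterministically toward the later file position. It is idempotent and
  applied per source — FAERS and JADER are never pooled.
* **Eligibility** keeps reports with known sex, known age, and age strictly
  greater than 20 years. JADER codes age only in decades, so exact years are
  unknowable there; the "20s" decade is *included* (decade lower edge ≥ 20),
  consistent with subgroup tables that start at the 20s band. A
  `faers_inclusive_boundary` flag switches year-valued ages to ≥ 20 for
  sensitivity checks, and `all_reports_mode` disables the demographic
  filters entirely (the all-reports sensitivity analysis).
* **Age bands** are 10-year floors composed into two analysis groups,
  20–60s and 70–90s. Ages of 100+ sit in a "100s" policy band belonging to
  neither group, mirroring subgroup tables that stop at the 90s; such
  reports still count in overall analyses.

## Event mapping

The outcome is a set of MedDRA preferred terms standing in for an SMQ
(impaired glucose metabolism = SMQ 20000041, 113 PTs). MedDRA is licensed,
so the PT list is always a user-supplied file; the packaged
`impaired_glucose_metabolism_synthetic_terms.txt` is a *synthetic* stand-in
with the right cardinality for testing, not MedDRA content. Matching is
exact string on trimmed, whitespace-collapsed, case-folded terms — no
hierarchy traversal, and no narrow/broad SMQ scope distinction (the flat
list is whatever scope the user exports).

## Time to onset

Among exposed event cases, the interval runs from the drug administration
start date to the event onset date, using the earliest resolvable date on
each side when several exist. Partial dates are common in JADER-style data:
year-month dates are imputed to the first of the month under the default
`impute_month_start` policy (or dropped under `strict`); year-only dates are
always dropped, since a half-year error would swamp the scale of interest.
Negative intervals (possible artefacts of month imputation or data entry)
are excluded with reason `onset_before_start`; every exclusion is tallied.

The Kaplan–Meier curve is fitted with `survival::survfit()`. Because the
analysis conditions on the event having been reported, there is no
censoring and the product-limit estimator reduces *exactly* to one minus the
empirical CDF — an identity the tests assert at every event time. An
`event_observed` hook accepts censored records for reuse beyond this design.

## The synthetic-data generator

`synthetic_config()` + `simulate_reports()` emulate an SRS extract with
known ground truth, so the whole pipeline can be validated without
downloading archives. Event assignment is on the *odds* scale: an exposed
case's event odds are the injected $ROR \times p_0/(1-p_0)$ (odds multiply
across exposures). This makes the injected parameter exactly the estimand
of the ROR estimator — a risk-ratio injection would not be, and parameter
recovery would then test the generator rather than the estimator.

Defaults, chosen once as a plausible adult oncology-weighted reporting
population and not tuned thereafter: background event probability 0.05
(real archives print 5.6–8.9% for this event set); focal-drug exposure
0.05; sex 48% male / 48% female / 4% missing; ages rounded from a normal
with mean 58, SD 17, truncated to 0–99, 5% missing; 10% of cases duplicated
as a strictly newer version with possibly amended fields (filling missing
sex, adding a reaction), exercising deduplication; exponential onset delays
with mean 150 days; 15% of dates degraded to year-month, exercising the
date policy; every case gets at least one drug (a 20-name concomitant pool)
and at least one reaction (a 30-name background PT pool).

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: correlated co-prescription, notoriety and
under-reporting bias, terminology drift across MedDRA versions, true
indication channeling, and Shift-JIS encodings (fixtures are UTF-8; the
dialect's encoding field accepts others).

## Numerical and design choices

* **Rounding for display** is half-up (2 decimals for ROR, 3 for CI
  bounds), matching conventional table presentation; base R's half-to-even
  `round()` differs at ties, hence `round_half_up()`. Full precision is
  retained in all computed columns.
* **Fisher tie handling**: outcome probabilities within a relative $10^{-7}$
  of the observed one count as ties, absorbing floating-point noise between
  mathematically equal tails (the same convention as `stats::fisher.test`,
  against which the implementation is cross-checked; an independent
  binomial-coefficient enumeration oracle is used in the acceptance tests).
  The enumeration is over the hypergeometric support, `min(margins) + 1`
  points, so million-report tables cost only thousands of terms; a normal
  approximation exists behind `support_threshold` but is effectively off.
* **Report recency** is the numeric order of the version key within a case;
  ties go to the later file position, deterministically.
* **Drug matching** is exact string on normalized names. No ingredient or
  trade-name dictionary is consulted; callers screening real extracts
  should pre-map synonyms.
* **Monte Carlo validation sizes.** Parameter recovery is validated on a
  grid of injected RORs {0.5, 1, 2, 4} with 100 replicates of 20,000 cases
  each; medians are checked per grid value (within 10% of truth) and Wald
  interval coverage is checked pooled over the 400 replicates, the budget
  at which a ±3-point band around the nominal 95% is resolvable (Monte
  Carlo SE ≈ 1.1%; any single 100-replicate slice has SE ≈ 2.2% and would
  falsely reject a correctly calibrated interval too often). Law-of-large-
  numbers checks of generator frequencies use one draw of 100,000 cases at
  a three-standard-error tolerance.

## Known limitations

* Published CI lower bounds in reference tables occasionally differ in the
  third decimal from recomputation under the stated formula (upper bounds
  match); point estimates reproduce exactly. Validation therefore anchors
  on point estimates, and recomputed bounds are used for signal
  classification.
* Dialect adapters target the fixture layouts; real FAERS quarters vary in
  columns and layout across years, which the column-map configuration
  absorbs only case by case.
* The screen treats drugs independently; interaction signals and shrinkage
  estimators (PRR, MGPS/EBGM, Bayesian IC) are out of scope.
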