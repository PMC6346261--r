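# rorscreen

Disproportionality signal screening for spontaneous adverse-event reports.

## The problem

Spontaneous reporting systems (SRS) — FAERS in the US, JADER in Japan —
collect voluntary reports of suspected adverse drug events. They carry no
denominators, so drug safety questions are asked as *disproportionality*
questions: is an event reported more often **among reports mentioning a
drug** than among all other reports? The motivating application is impaired
glucose metabolism under BCR-ABL inhibitors (imatinib, dasatinib, nilotinib,
bosutinib, ponatinib) in chronic myeloid leukemia, where nilotinib alone
shows a reporting signal.

`rorscreen` implements the full screening pipeline for analysts working with
FAERS- or JADER-style extracts:

1. **I/O** — dialect-driven readers/writers for `$`-delimited FAERS-style and
   comma-delimited JADER-style demo/drug/reac tables, assembled into one
   tidy report tibble per case version.
2. **Preprocessing** — deduplication to the latest report version per case,
   eligibility filters (complete sex and age, age strictly over 20 years),
   10-year age bands composed into 20–60s / 70–90s groups.
3. **Event mapping** — case-level membership in an outcome event set defined
   by a user-supplied MedDRA preferred-term list (standing in for an SMQ;
   MedDRA content is licensed and never bundled — a clearly synthetic
   113-term stand-in ships for testing).
4. **Disproportionality** — the reporting odds ratio per drug and stratum,
   with Wald 95% CI, strict lower-bound signal rule, and a two-sided Fisher
   exact p-value.
5. **Time to onset** — days from drug start to event onset among exposed
   event cases, summarized by the Kaplan–Meier product-limit curve.
6. **Synthetic data** — an SRS emulator with known injected reporting odds
   ratios, duplicates, missingness and partial dates, so every stage is
   verifiable end to end with no archive downloads.

## The statistic

For the 2×2 table cross-classifying reports by drug exposure and event
membership within a stratum,

|              | event | no event |
|--------------|-------|----------|
| drug         | n11   | n12      |
| all others   | n21   | n22      |

the reporting odds ratio and its Wald interval are

    ROR = (n11/n21) / (n12/n22)
    95% CI = exp{ ln ROR ± 1.96 · sqrt(1/n11 + 1/n12 + 1/n21 + 1/n22) }

and a signal is declared when the CI lower bound exceeds 1 (strictly). A ROR
measures reporting disproportionality, not risk, and implies no causality.

## Worked example

Published report counts for the BCR-ABL inhibitors ship as a fixture;
feeding any row's counts to the estimator reproduces the published
estimates:

```r
library(rorscreen)

# overall nilotinib row of the FAERS extract:
# 514 of 5,122 nilotinib reports had an impaired-glucose-metabolism term,
# 176,446 of 2,170,873 other reports did
ror_ci(n11 = 514, n12 = 5122 - 514, n21 = 176446, n22 = 2170873 - 176446)
#> # A tibble: 1 × 4
#>     ror ci_low ci_high reason
#>   <dbl>  <dbl>   <dbl> <chr>
#> 1  1.26   1.15    1.38 NA
```

The ROR of 1.26 with a lower bound above 1 is a signal: impaired glucose
metabolism is over-represented among nilotinib reports. The same call on the
imatinib row gives 0.79 (CI entirely below 1) — no signal.

An end-to-end run on synthetic data with one injected signal:

```r
cfg <- synthetic_config(
  n_cases = 20000, seed = 42,
  drug_specs = data.frame(
    drug_name = c("nilotinib", "imatinib"),
    exposure_prob = c(0.05, 0.05),
    true_ror = c(2, 1)
  )
)
terms <- read_term_set(system.file(
  "extdata", "impaired_glucose_metabolism_synthetic_terms.txt",
  package = "rorscreen"
))
reports <- simulate_reports(cfg) |>
  deduplicate_reports() |>
  apply_eligibility()
screen <- ror_screen(reports, c("nilotinib", "imatinib"), terms,
                     strata = list(stratum_spec()))
tidy(screen)
#> # A tibble: 2 × 7
#>   drug      stratum estimate conf.low conf.high     p.value signal
#>   <chr>     <chr>      <dbl>    <dbl>     <dbl>       <dbl> <lgl>
#> 1 nilotinib overall    1.93     1.52       2.46 0.000000769 TRUE
#> 2 imatinib  overall    0.924    0.680      1.26 0.704       FALSE
```

Only the drug with the injected effect is flagged. `autoplot(screen)` draws
the forest plot; `run_pipeline()` drives the whole flow (including the
Kaplan–Meier time-to-onset step and QC artifacts) from one YAML config —
see `inst/extdata/demo_config.yaml`.

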