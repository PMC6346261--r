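Package: rorscreen
Title: Disproportionality Signal Screening for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pharmacovigilance signal detection from spontaneous reporting
    system extracts in FAERS- and JADER-style table layouts: report
    deduplication to the latest case version, demographic eligibility
    filtering, preferred-term event-set mapping in place of licensed SMQ
    content, reporting odds ratio (ROR) screening with Wald confidence
    intervals and two-sided Fisher exact tests, subgroup stratification by
    sex and 10-year age bands, time-to-onset Kaplan-Meier summaries, and a
    synthetic report generator with known injected reporting odds ratios so
    the whole pipeline can be validated end to end without access to the
    real archives.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    survival,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
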