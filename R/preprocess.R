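#' Deduplicate reports to the latest case version
#'
#' Spontaneous reporting archives accumulate multiple report versions per
#' case as follow-up information arrives; FAERS guidance is to analyse only
#' the latest version. This keeps, for every case identifier, the row with
#' the maximal version key (ties broken by file order, keeping the last
#' occurrence — deterministic), and sorts the result by case identifier.
#' The operation is idempotent and is always applied within one source;
#' FAERS and JADER report sets are never pooled.
#'
#' @param reports An `srs_reports` tibble (one row per case version).
#' @return An `srs_reports` tibble with exactly one row per `case_id`.
#' @export
#' @examples
#' r <- simulate_reports(synthetic_config(n_cases = 100, seed = 1))
#' nrow(deduplicate_reports(r))
deduplicate_reports <- function(reports) {
  stopifnot(is.data.frame(reports))
  # stable sort by (case_id, version, file order), then keep the last row of
  # each case: the maximal version, ties resolved to the later occurrence
  ord <- order(reports$case_id, reports$version, method = "radix")
  sorted <- reports[ord, ]
  as_srs_reports(sorted[!duplicated(sorted$case_id, fromLast = TRUE), ])
}

#' Eligibility filter settings
#'
#' The primary analysis keeps only reports with complete sex and age
#' information and patient age strictly greater than 20 years. For decade-
#' coded ages (JADER), where exact years are unknown, the "20s" decade is
#' included: a decade code qualifies iff its lower edge is at least 20.
#' `all_reports_mode` disables every demographic filter, reproducing the
#' sensitivity analysis on all reports.
#'
#' @param require_sex,require_age Require the field to be present.
#' @param min_age_years Exclusive lower age bound for year-valued ages.
#' @param faers_inclusive_boundary If `TRUE`, year-valued ages use `>=`
#'   instead of `>` at the boundary (sensitivity check).
#' @param all_reports_mode Disable all demographic filters.
#' @return A list of class `eligibility_config`.
#' @export
eligibility_config <- function(require_sex = TRUE,
                               require_age = TRUE,
                               min_age_years = 20,
                               faers_inclusive_boundary = FALSE,
                               all_reports_mode = FALSE) {
  stopifnot(min_age_years >= 0)
  structure(
    list(
      require_sex = require_sex, require_age = require_age,
      min_age_years = min_age_years,
      faers_inclusive_boundary = faers_inclusive_boundary,
      all_reports_mode = all_reports_mode
    ),
    class = "eligibility_config"
  )
}

#' Apply demographic eligibility filters
#'
#' @param reports A deduplicated `srs_reports` tibble.
#' @param config An [eligibility_config()].
#' @return The retained reports, with attribute `qc`: named counts of
#'   reports excluded by each filter (evaluated in sequence: missing sex,
#'   missing age, age at or under the bound).
#' @export
apply_eligibility <- function(reports, config = eligibility_config()) {
  stopifnot(is.data.frame(reports), inherits(config, "eligibility_config"))
  if (config$all_reports_mode) {
    out <- as_srs_reports(reports)
    attr(out, "qc") <- c(excluded_missing_sex = 0L, excluded_missing_age = 0L,
                         excluded_age_bound = 0L)
    return(out)
  }
  has_age <- !is.na(reports$age_years) | !is.na(reports$age_decade)
  keep <- rep(TRUE, nrow(reports))
  drop_sex <- config$require_sex & is.na(reports$sex)
  keep <- keep & !drop_sex
  drop_age <- keep & config$require_age & !has_age
  keep <- keep & !drop_age
  # year-valued ages: strictly greater than the bound (">= " as sensitivity
  # option); decade codes qualify iff the decade lower edge >= bound
  year_ok <- if (config$faers_inclusive_boundary) {
    reports$age_years >= config$min_age_years
  } else {
    reports$age_years > config$min_age_years
  }
  age_ok <- dplyr::case_when(
    !is.na(reports$age_years) ~ year_ok,
    !is.na(reports$age_decade) ~ reports$age_decade >= config$min_age_years,
    TRUE ~ !config$require_age
  )
  drop_bound <- keep & !age_ok
  keep <- keep & !drop_bound
  out <- as_srs_reports(reports[keep, ])
  attr(out, "qc") <- c(
    excluded_missing_sex = sum(drop_sex),
    excluded_missing_age = sum(drop_age),
    excluded_age_bound = sum(drop_bound)
  )
  out
}

#' 10-year age bands and the two analysis age groups
#'
#' Subgroup analyses use 10-year age bands (JADER records age only at that
#' resolution) combined into two groups: 20s-60s and 70s-90s. Year-valued
#' ages map to the band `floor(age/10)*10`; decade codes map directly.
#' Ages of 100 and over fall in a "100s" policy band that belongs to
#' neither analysis group, matching subgroup tables that stop at the 90s.
#'
#' @param reports An `srs_reports` tibble.
#' @return `age_band()`: character vector of band labels (`"0s"` ...
#'   `"90s"`, `"100s"`, `NA` when age is missing). `age_group()`: character
#'   vector `"20-60s"`, `"70-90s"` or `NA`.
#' @export
#' @examples
#' r <- simulate_reports(synthetic_config(n_cases = 50, seed = 2))
#' table(age_band(r), useNA = "ifany")
age_band <- function(reports) {
  low <- ifelse(
    !is.na(reports$age_decade),
    reports$age_decade,
    floor(reports$age_years / 10) * 10
  )
  low <- pmin(low, 100)
  ifelse(is.na(low), NA_character_, paste0(low, "s"))
}

#' @rdname age_band
#' @export
age_group <- function(reports) {
  band_to_group(age_band(reports))
}

band_to_group <- function(band) {
  low <- suppressWarnings(as.integer(sub("s$", "", band)))
  dplyr::case_when(
    !is.na(low) & low >= 20 & low <= 60 ~ "20-60s",
    !is.na(low) & low >= 70 & low <= 90 ~ "70-90s",
    TRUE ~ NA_character_
  )
}
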