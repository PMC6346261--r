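#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when formatting reporting odds
#' ratios and confidence bounds for display. Base [round()] rounds half to
#' even, which differs at exact .5 ties (e.g. `round(1.265, 2)`).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(1.265, 0.645), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the 1e-9 relative nudge absorbs binary representation error just below .5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Normalize a drug name or MedDRA preferred term
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace
#' to a single space, and case-folds to lower case. All name matching in the
#' package (drug exposure, event-set membership) is exact-string on the
#' normalized form; no ingredient or terminology dictionary is consulted.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_term(c("  Hyperglycaemia ", "Blood   Glucose Increased"))
normalize_term <- function(x) {
  stringr::str_to_lower(stringr::str_squish(x))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Shared column order for report tibbles.
.report_cols <- c(
  "source", "case_id", "version", "sex", "age_years", "age_decade",
  "drugs", "drug_starts", "reactions", "reaction_onsets"
)

as_srs_reports <- function(x) {
  stopifnot(is.data.frame(x), all(.report_cols %in% names(x)))
  x <- tibble::as_tibble(x)[, .report_cols]
  class(x) <- unique(c("srs_reports", class(x)))
  x
}

#' @export
print.srs_reports <- function(x, ...) {
  cat(sprintf(
    "<srs_reports: %d report rows, %d distinct cases>\n",
    nrow(x), dplyr::n_distinct(x$case_id)
  ))
  NextMethod()
}
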