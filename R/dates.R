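#' Parse partial ISO dates
#'
#' Spontaneous-report archives frequently record dates with reduced
#' precision: JADER in particular carries many year-month and year-only
#' entries. The package's canonical representation is an ISO-like string
#' with only the known components: `"2015-03-02"`, `"2015-03"` or `"2015"`.
#' This parser splits such strings into their numeric components without
#' guessing the missing ones.
#'
#' @param x Character vector of partial dates (`""` and `NA` allowed).
#' @return A tibble with integer columns `year`, `month`, `day` (`NA` where
#'   the component is absent) and a logical `valid` column. A date is valid
#'   when it matches the partial pattern, the month is 1-12 and, for complete
#'   dates, the day exists in that calendar month.
#' @export
#' @examples
#' parse_partial_date(c("2015-03-02", "2015-03", "2015", "2015-02-30", ""))
parse_partial_date <- function(x) {
  x <- as.character(x)
  m <- stringr::str_match(x, "^(\\d{4})(?:-(\\d{1,2})(?:-(\\d{1,2}))?)?$")
  year <- as.integer(m[, 2])
  month <- as.integer(m[, 3])
  day <- as.integer(m[, 4])
  valid <- !is.na(year)
  valid[!is.na(month) & (month < 1 | month > 12)] <- FALSE
  complete <- valid & !is.na(month) & !is.na(day)
  if (any(complete)) {
    d <- as.Date(
      sprintf("%04d-%02d-%02d", year[complete], month[complete], day[complete]),
      format = "%Y-%m-%d"
    )
    valid[complete][is.na(d)] <- FALSE
  }
  year[!valid] <- NA_integer_
  month[!valid] <- NA_integer_
  day[!valid] <- NA_integer_
  tibble::tibble(year = year, month = month, day = day, valid = valid)
}

#' Resolve partial dates to calendar dates under a policy
#'
#' Time-to-onset intervals need actual calendar dates. Complete dates are
#' used as-is. Year-month dates are either imputed to the first of the month
#' (policy `"impute_month_start"`, the default) or dropped (policy
#' `"strict"`). Year-only dates are always dropped: a potential error of up
#' to half a year would swamp the onset-time scale of interest.
#'
#' @param x Character vector of partial dates.
#' @param policy `"impute_month_start"` or `"strict"`.
#' @return A tibble with columns `date` ([Date], `NA` when unresolvable),
#'   `quality` (`"complete"`, `"imputed_month"`, `"excluded"`) and `reason`
#'   (`NA` or one of `"missing"`, `"unparseable"`, `"year_only"`,
#'   `"month_only_strict"`).
#' @export
resolve_partial_date <- function(x, policy = c("impute_month_start", "strict")) {
  policy <- match.arg(policy)
  p <- parse_partial_date(x)
  n <- nrow(p)
  date <- rep(as.Date(NA), n)
  quality <- rep("excluded", n)
  reason <- rep(NA_character_, n)

  missing <- is.na(x) | x == ""
  reason[missing] <- "missing"
  reason[!missing & !p$valid] <- "unparseable"

  complete <- p$valid & !is.na(p$month) & !is.na(p$day)
  date[complete] <- as.Date(sprintf(
    "%04d-%02d-%02d", p$year[complete], p$month[complete], p$day[complete]
  ))
  quality[complete] <- "complete"

  ym <- p$valid & !is.na(p$month) & is.na(p$day)
  if (policy == "impute_month_start") {
    date[ym] <- as.Date(sprintf("%04d-%02d-01", p$year[ym], p$month[ym]))
    quality[ym] <- "imputed_month"
  } else {
    reason[ym] <- "month_only_strict"
  }

  y_only <- p$valid & is.na(p$month)
  reason[y_only] <- "year_only"

  tibble::tibble(date = date, quality = quality, reason = reason)
}
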