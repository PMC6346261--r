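#' Define an analysis stratum
#'
#' A stratum restricts the report set before the 2x2 table is built:
#' optionally by sex and/or by the composite age group (see [age_group()]).
#' An empty spec is the overall analysis.
#'
#' @param sex `NULL`, `"male"` or `"female"`.
#' @param age_group `NULL`, `"20-60s"` or `"70-90s"`.
#' @param label Display label; derived from the filters when omitted.
#' @return A list of class `stratum_spec`.
#' @export
stratum_spec <- function(sex = NULL, age_group = NULL, label = NULL) {
  if (!is.null(sex)) sex <- match.arg(sex, c("male", "female"))
  if (!is.null(age_group)) age_group <- match.arg(age_group, c("20-60s", "70-90s"))
  if (is.null(label)) {
    parts <- c(sex, age_group)
    label <- if (length(parts)) paste(parts, collapse = "/") else "overall"
  }
  structure(list(sex = sex, age_group = age_group, label = label),
            class = "stratum_spec")
}

#' @rdname stratum_spec
#' @details `default_strata()` is the standard screen layout: overall, both
#'   sexes, and both age groups (five strata).
#' @export
default_strata <- function() {
  list(
    stratum_spec(),
    stratum_spec(sex = "male"),
    stratum_spec(sex = "female"),
    stratum_spec(age_group = "20-60s"),
    stratum_spec(age_group = "70-90s")
  )
}

stratum_mask <- function(reports, stratum, groups = NULL) {
  keep <- rep(TRUE, nrow(reports))
  if (!is.null(stratum$sex)) {
    keep <- keep & !is.na(reports$sex) & reports$sex == stratum$sex
  }
  if (!is.null(stratum$age_group)) {
    if (is.null(groups)) groups <- age_group(reports)
    keep <- keep & !is.na(groups) & groups == stratum$age_group
  }
  keep
}

#' Build the 2x2 contingency table for one drug and event set
#'
#' Within the stratum, every report falls in exactly one cell of the table
#' cross-classifying drug exposure (the normalized drug name appears in the
#' report's drug list) against outcome event membership ([has_event()]):
#' `n11` exposed with event, `n12` exposed without, `n21` unexposed with
#' event, `n22` unexposed without. The comparator is all other reports in
#' the same source and stratum.
#'
#' @param reports Deduplicated, eligibility-filtered `srs_reports`.
#' @param drug_name Drug name (normalized internally).
#' @param terms A [term_set()].
#' @param stratum A [stratum_spec()].
#' @param event Optional precomputed logical event vector (along
#'   `reports`), to avoid rescanning reactions in repeated calls.
#' @return A one-row tibble: `drug`, `stratum`, `n11`, `n12`, `n21`, `n22`.
#' @export
#' @examples
#' r <- deduplicate_reports(simulate_reports(synthetic_config(n_cases = 500, seed = 3)))
#' contingency_table(r, "drug_a", term_set(c("hyperglycaemia", "diabetes mellitus")))
contingency_table <- function(reports, drug_name, terms,
                              stratum = stratum_spec(), event = NULL) {
  stopifnot(is.data.frame(reports))
  drug_name <- normalize_term(drug_name)
  if (is.null(event)) event <- has_event(reports, terms)
  exposed <- report_exposed(reports, drug_name)
  keep <- stratum_mask(reports, stratum)
  tibble::tibble(
    drug = drug_name,
    stratum = stratum$label,
    n11 = sum(keep & exposed & event),
    n12 = sum(keep & exposed & !event),
    n21 = sum(keep & !exposed & event),
    n22 = sum(keep & !exposed & !event)
  )
}

report_exposed <- function(reports, drug_name) {
  d <- unlist(reports$drugs, use.names = FALSE)
  if (!length(d)) return(rep(FALSE, nrow(reports)))
  idx <- rep.int(seq_len(nrow(reports)), lengths(reports$drugs))
  out <- rep(FALSE, nrow(reports))
  out[unique(idx[d == drug_name])] <- TRUE
  out
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' The reporting odds ratio for a 2x2 report table is
#' \deqn{ROR = \frac{n_{11}/n_{21}}{n_{12}/n_{22}},}
#' with the Wald interval on the log scale,
#' \deqn{95\%\,CI = \exp\{\ln ROR \pm 1.96\sqrt{1/n_{11}+1/n_{12}+1/n_{21}+1/n_{22}}\},}
#' using the natural logarithm and z fixed at exactly 1.96. When any cell is
#' zero the estimate is undefined and returned as `NA` with reason
#' `"zero_cell"` — reporting `-` there matches surveillance practice, and no
#' continuity correction is applied unless `haldane = TRUE` adds 0.5 to
#' every cell (a convention option, not part of the reference analysis).
#'
#' All arguments are vectorized.
#'
#' @param n11,n12,n21,n22 Cell counts, or a data frame with those columns
#'   as the first argument.
#' @param haldane Apply the +0.5 Haldane-Anscombe correction.
#' @return A tibble: `ror`, `ci_low`, `ci_high`, `reason` (`NA` or
#'   `"zero_cell"`).
#' @export
#' @examples
#' ror_ci(514, 4608, 176446, 1994427)
ror_ci <- function(n11, n12 = NULL, n21 = NULL, n22 = NULL, haldane = FALSE) {
  if (is.data.frame(n11)) {
    tab <- n11
    n11 <- tab$n11; n12 <- tab$n12; n21 <- tab$n21; n22 <- tab$n22
  }
  stopifnot(all(c(n11, n12, n21, n22) >= 0))
  if (haldane) {
    n11 <- n11 + 0.5; n12 <- n12 + 0.5; n21 <- n21 + 0.5; n22 <- n22 + 0.5
  }
  zero <- n11 == 0 | n12 == 0 | n21 == 0 | n22 == 0
  ror <- ifelse(zero, NA_real_, (n11 / n21) / (n12 / n22))
  se <- ifelse(zero, NA_real_, sqrt(1 / n11 + 1 / n12 + 1 / n21 + 1 / n22))
  tibble::tibble(
    ror = ror,
    ci_low = exp(log(ror) - 1.96 * se),
    ci_high = exp(log(ror) + 1.96 * se),
    reason = ifelse(zero, "zero_cell", NA_character_)
  )
}

#' Signal rule: CI lower bound strictly above one
#'
#' A disproportionality signal is declared when the lower limit of the ROR's
#' 95% confidence interval exceeds one (strict inequality; a bound of
#' exactly 1 is not a signal). Undefined estimates never signal.
#'
#' @param ror,ci_low Point estimate and lower bound (vectorized). `ror` may
#'   also be a data frame with columns `ror`, `ci_low`.
#' @return Logical vector.
#' @export
detect_signal <- function(ror, ci_low = NULL) {
  if (is.data.frame(ror)) {
    ci_low <- ror$ci_low
  }
  !is.na(ci_low) & ci_low > 1
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact conditional test with both margins fixed: over the hypergeometric
#' support, the two-sided p-value sums the probabilities of all outcomes no
#' more probable than the observed table (the point-probability method,
#' the conventional two-sided definition). Probabilities within a relative
#' 1e-7 of the observed one are treated as ties, absorbing floating-point
#' noise between mathematically equal tails. The enumeration touches only
#' `min(margins) + 1` support points, so it stays exact even for
#' million-report tables; above `support_threshold` support points a normal
#' approximation to the hypergeometric is used instead (effectively off by
#' default).
#'
#' @param n11,n12,n21,n22 Cell counts (vectorized), or a data frame with
#'   those columns as the first argument.
#' @param support_threshold Support size above which the normal
#'   approximation is used.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
#' @examples
#' fisher_exact_p(1, 1, 1, 1)
fisher_exact_p <- function(n11, n12 = NULL, n21 = NULL, n22 = NULL,
                           support_threshold = 1e7) {
  if (is.data.frame(n11)) {
    tab <- n11
    n11 <- tab$n11; n12 <- tab$n12; n21 <- tab$n21; n22 <- tab$n22
  }
  stopifnot(all(c(n11, n12, n21, n22) >= 0))
  mapply(fisher_exact_p_one, n11, n12, n21, n22,
         MoreArgs = list(support_threshold = support_threshold))
}

fisher_exact_p_one <- function(n11, n12, n21, n22, support_threshold) {
  m <- n11 + n12      # exposed reports (white balls)
  nn <- n21 + n22     # unexposed reports (black balls)
  k <- n11 + n21      # event reports (draws)
  if (m == 0 || nn == 0 || k == 0 || k == m + nn) return(1)
  lo <- max(0, k - nn)
  hi <- min(k, m)
  if (hi - lo + 1 > support_threshold) {
    total <- m + nn
    mu <- k * m / total
    v <- k * (m / total) * (nn / total) * (total - k) / (total - 1)
    return(min(1, 2 * stats::pnorm(-abs(n11 - mu) / sqrt(v))))
  }
  x <- lo:hi
  d <- stats::dhyper(x, m, nn, k)
  d_obs <- stats::dhyper(n11, m, nn, k)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Screen drugs for disproportionality signals
#'
#' Runs the full signal-detection screen: for every drug and every stratum,
#' build the 2x2 table against all other reports in that stratum, compute
#' the ROR with its Wald 95% CI, apply the signal rule, and attach the
#' two-sided Fisher exact p-value. No multiple-testing adjustment is
#' applied (signals are reported unadjusted, as is conventional for
#' hypothesis-generating SRS screens); the comparator keeps reports exposed
#' to the other screened drugs unless `exclude_class = TRUE` removes every
#' screened drug from the reference cells.
#'
#' @param reports Deduplicated, eligibility-filtered `srs_reports`.
#' @param drugs Character vector of drug names to screen.
#' @param terms A [term_set()].
#' @param strata List of [stratum_spec()]s (default: overall, sexes, age
#'   groups).
#' @param exclude_class Drop reports exposed to any other screened drug
#'   from the comparator cells.
#' @return A tibble of class `ror_screen`, one row per drug-stratum:
#'   `source`, `drug`, `event_set`, `stratum`, the four cells, `ror`,
#'   `ci_low`, `ci_high`, `signal`, `fisher_p`, `reason`.
#' @export
#' @examples
#' r <- simulate_reports(synthetic_config(n_cases = 2000, seed = 5)) |>
#'   deduplicate_reports() |>
#'   apply_eligibility()
#' ror_screen(r, "drug_a", term_set(c("hyperglycaemia", "diabetes mellitus")),
#'            strata = list(stratum_spec()))
ror_screen <- function(reports, drugs, terms, strata = default_strata(),
                       exclude_class = FALSE) {
  stopifnot(is.data.frame(reports), inherits(terms, "term_set"))
  drugs <- normalize_term(drugs)
  if (!length(drugs)) {
    return(empty_screen())
  }
  event <- has_event(reports, terms)
  groups <- age_group(reports)
  expo <- lapply(drugs, function(d) report_exposed(reports, d))
  names(expo) <- drugs
  any_expo <- Reduce(`|`, expo, rep(FALSE, nrow(reports)))
  src <- if (nrow(reports)) reports$source[1] else NA_character_

  grid <- expand.grid(si = seq_along(strata), di = seq_along(drugs))
  rows <- purrr::pmap(grid, function(si, di) {
    stratum <- strata[[si]]
    keep <- stratum_mask(reports, stratum, groups)
    e <- expo[[di]]
    comp <- if (exclude_class) !any_expo else !e
    tibble::tibble(
      source = src,
      drug = drugs[di],
      event_set = terms$name,
      stratum = stratum$label,
      n11 = sum(keep & e & event),
      n12 = sum(keep & e & !event),
      n21 = sum(keep & comp & event),
      n22 = sum(keep & comp & !event)
    )
  })
  out <- dplyr::bind_rows(rows)
  est <- ror_ci(out)
  out$ror <- est$ror
  out$ci_low <- est$ci_low
  out$ci_high <- est$ci_high
  out$signal <- detect_signal(est)
  out$fisher_p <- fisher_exact_p(out)
  out$reason <- est$reason
  class(out) <- unique(c("ror_screen", class(out)))
  attr(out, "term_set") <- list(name = terms$name, smq_id = terms$smq_id,
                                n_terms = length(terms$terms))
  out
}

empty_screen <- function() {
  out <- tibble::tibble(
    source = character(), drug = character(), event_set = character(),
    stratum = character(), n11 = integer(), n12 = integer(),
    n21 = integer(), n22 = integer(), ror = numeric(), ci_low = numeric(),
    ci_high = numeric(), signal = logical(), fisher_p = numeric(),
    reason = character()
  )
  class(out) <- unique(c("ror_screen", class(out)))
  out
}

#' Tidy and summarize a screen result
#'
#' `tidy()` returns the per-(drug, stratum) estimates in long broom-style
#' form; `glance()` gives one row of screen-level summary.
#'
#' @param x A `ror_screen` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ror_screen
#' @export
tidy.ror_screen <- function(x, ...) {
  tibble::tibble(
    drug = x$drug,
    stratum = x$stratum,
    estimate = x$ror,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    p.value = x$fisher_p,
    signal = x$signal
  )
}

#' @rdname tidy.ror_screen
#' @method glance ror_screen
#' @export
glance.ror_screen <- function(x, ...) {
  tibble::tibble(
    n_drugs = dplyr::n_distinct(x$drug),
    n_strata = dplyr::n_distinct(x$stratum),
    n_signals = sum(x$signal, na.rm = TRUE),
    n_undefined = sum(!is.na(x$reason))
  )
}

#' Forest plot of a screen result
#'
#' One point and 95% CI per drug, faceted by stratum, on a log axis, with
#' the signal threshold at ROR = 1 marked.
#'
#' @param object A `ror_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ror_screen
#' @export
autoplot.ror_screen <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$ror), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ror, y = .data$drug,
                                  colour = .data$signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL,
                  colour = "Signal") +
    ggplot2::theme_minimal()
}
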