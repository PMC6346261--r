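#' Extract time-to-onset records for one drug and event set
#'
#' For every report exposed to the drug and belonging to the event set,
#' computes the days from the drug administration start date to the adverse
#' event onset date. When a report carries several matching drug entries or
#' event reactions, the earliest resolvable start and the earliest
#' resolvable onset are used (deterministic and conservative). Dates are
#' resolved under [resolve_partial_date()]'s policy; records whose interval
#' is negative are excluded with reason `"onset_before_start"`. Every
#' exclusion carries a reason code, tallied in the `qc` attribute.
#'
#' @param reports Deduplicated, eligibility-filtered `srs_reports`.
#' @param drug_name Drug to analyse.
#' @param terms A [term_set()] defining the event.
#' @param date_policy `"impute_month_start"` (year-month dates count, with
#'   day imputed to 1) or `"strict"` (complete dates only).
#' @return A tibble: `case_id`, `drug_name`, `days_to_onset`,
#'   `event_observed` (all `TRUE`; hook for censored reuse),
#'   `date_quality` (`"complete"` or `"imputed_month"`, the worse of the
#'   two dates). Attributes: `excluded` (tibble of case_id + reason), `qc`
#'   (named counts).
#' @export
extract_onsets <- function(reports, drug_name, terms,
                           date_policy = c("impute_month_start", "strict")) {
  date_policy <- match.arg(date_policy)
  drug_name <- normalize_term(drug_name)
  exposed <- report_exposed(reports, drug_name)
  event <- has_event(reports, terms)
  cand <- reports[exposed & event, ]

  n <- nrow(cand)
  start <- rep(as.Date(NA), n)
  start_q <- rep(NA_character_, n)
  onset <- rep(as.Date(NA), n)
  onset_q <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    di <- cand$drugs[[i]] == drug_name
    s <- resolve_partial_date(cand$drug_starts[[i]][di], date_policy)
    if (any(!is.na(s$date))) {
      j <- which.min(s$date)
      start[i] <- s$date[j]
      start_q[i] <- s$quality[j]
    }
    ri <- normalize_term(cand$reactions[[i]]) %in% terms$terms
    o <- resolve_partial_date(cand$reaction_onsets[[i]][ri], date_policy)
    if (any(!is.na(o$date))) {
      j <- which.min(o$date)
      onset[i] <- o$date[j]
      onset_q[i] <- o$quality[j]
    }
  }

  days <- as.numeric(onset - start)
  reason <- dplyr::case_when(
    is.na(start) ~ "no_resolvable_start_date",
    is.na(onset) ~ "no_resolvable_onset_date",
    days < 0 ~ "onset_before_start",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  quality <- ifelse(start_q == "imputed_month" | onset_q == "imputed_month",
                    "imputed_month", "complete")
  out <- tibble::tibble(
    case_id = cand$case_id[keep],
    drug_name = drug_name,
    days_to_onset = days[keep],
    event_observed = TRUE,
    date_quality = quality[keep]
  )
  excluded <- tibble::tibble(case_id = cand$case_id[!keep], reason = reason[!keep])
  attr(out, "excluded") <- excluded
  attr(out, "qc") <- c(
    exposed_event_cases = n,
    table(factor(excluded$reason, levels = c(
      "no_resolvable_start_date", "no_resolvable_onset_date", "onset_before_start"
    )))
  )
  out
}

#' Kaplan-Meier estimate of time to onset
#'
#' Product-limit estimate of the onset-time distribution via
#' [survival::survfit()]. In the reference setting every record is an
#' observed event (the analysis conditions on the event having been
#' reported), so the curve reduces exactly to one minus the empirical CDF
#' of the onset times; the `event_observed` column is honoured so censored
#' reuse is possible.
#'
#' @param records A tibble from [extract_onsets()] (needs `days_to_onset`
#'   and optionally `event_observed`).
#' @return An object of class `tto_km`: list with `steps` (tibble `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival` at each event time),
#'   `n_records`, `drug`.
#' @export
km_fit <- function(records) {
  if (!nrow(records)) stop("no_onset_records", call. = FALSE)
  obs <- if ("event_observed" %in% names(records)) records$event_observed else TRUE
  fit <- survival::survfit(
    survival::Surv(records$days_to_onset, rep(obs, length.out = nrow(records))) ~ 1
  )
  keep <- fit$n.event > 0
  steps <- tibble::tibble(
    time = fit$time[keep],
    n_risk = fit$n.risk[keep],
    n_event = fit$n.event[keep],
    n_censor = fit$n.censor[keep],
    survival = fit$surv[keep]
  )
  structure(
    list(
      steps = steps,
      n_records = nrow(records),
      drug = if ("drug_name" %in% names(records) && nrow(records)) {
        records$drug_name[1]
      } else {
        NA_character_
      }
    ),
    class = "tto_km"
  )
}

#' @export
print.tto_km <- function(x, ...) {
  cat(sprintf(
    "<tto_km: %d onset records, %d event times, median %s days>\n",
    x$n_records, nrow(x$steps), format(km_median(x))
  ))
  invisible(x)
}

km_median <- function(x) {
  below <- x$steps$time[x$steps$survival <= 0.5]
  if (length(below)) min(below) else NA_real_
}

#' @rdname km_fit
#' @param x A `tto_km` object.
#' @param ... Unused.
#' @method tidy tto_km
#' @export
tidy.tto_km <- function(x, ...) {
  x$steps
}

#' @rdname km_fit
#' @method glance tto_km
#' @export
glance.tto_km <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    n_event_times = nrow(x$steps),
    median_days = km_median(x),
    max_days = max(x$steps$time)
  )
}

#' Step plot of a Kaplan-Meier onset curve
#'
#' @param object A `tto_km` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tto_km
#' @export
autoplot.tto_km <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    object$steps[, c("time", "survival")]
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Days from drug administration start",
      y = "Proportion not yet reported",
      title = if (!is.na(object$drug)) {
        paste("Time to onset:", object$drug)
      } else {
        "Time to onset"
      }
    ) +
    ggplot2::theme_minimal()
}

#' Export / re-import a Kaplan-Meier step table
#'
#' Writes the step function as a CSV (`time`, `n_risk`, `n_event`,
#' `n_censor`, `survival`) and optionally renders the step plot to an image
#' file. `read_km_table()` reads the CSV back.
#'
#' @param est A `tto_km` object.
#' @param path Output CSV path.
#' @param plot_path Optional image path (any device [ggplot2::ggsave()]
#'   supports).
#' @return `path`, invisibly.
#' @export
km_export <- function(est, path, plot_path = NULL) {
  stopifnot(inherits(est, "tto_km"))
  readr::write_csv(est$steps, path)
  if (!is.null(plot_path)) {
    ggplot2::ggsave(plot_path, autoplot(est), width = 6, height = 4)
  }
  invisible(path)
}

#' @rdname km_export
#' @export
read_km_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      time = "d", n_risk = "i", n_event = "i", n_censor = "i", survival = "d"
    ),
    progress = FALSE
  )
}
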