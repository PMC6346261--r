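#' Configuration for the synthetic report generator
#'
#' Describes an SRS-like population with known ground truth. Exposure to
#' each configured drug is an independent Bernoulli draw; the outcome event
#' is then assigned on the odds scale: a case exposed to a drug with
#' injected reporting odds ratio \eqn{r} has event odds \eqn{r \times
#' p_0/(1-p_0)} where \eqn{p_0} is the background event probability (odds
#' multiply across exposures). Generating on the odds scale makes the
#' injected parameter exactly the estimand of the reporting-odds-ratio
#' estimator, so parameter-recovery checks are meaningful.
#'
#' Defaults sketch a plausible adult pharmacovigilance population: a 5%
#' background reporting proportion for the outcome event set (the real
#' archives print 5.6%-8.9% for impaired glucose metabolism), exposure of a
#' focal drug in 5% of reports, a near-even sex split with a small missing
#' mass, ages from a truncated normal centred at 58 (SD 17, clipped to
#' 0-99, 5% missing) mimicking an older oncology-weighted reporting
#' population, 10% duplicated cases, exponential onset delays with mean 150
#' days, and 15% of dates carried at year-month precision only.
#'
#' @param n_cases Number of distinct cases.
#' @param seed Integer seed; the generator is deterministic given the
#'   config (same seed and settings give byte-identical output).
#' @param background_event_prob Event probability among unexposed cases.
#' @param drug_specs Data frame with columns `drug_name`, `exposure_prob`,
#'   `true_ror`.
#' @param sex_probs Named numeric `c(male=, female=, missing=)`, summing to 1.
#' @param age_mean,age_sd,age_missing_prob Age model (years; truncated to
#'   0-99 and rounded).
#' @param duplicate_prob Probability a case gets a second, newer report
#'   version (exercising deduplication).
#' @param onset_model List: `family` `"exponential"` (uses `scale` = mean
#'   days) or `"weibull"` (uses `shape`, `scale`).
#' @param partial_date_prob Probability a date is degraded to year-month.
#' @param event_terms Preferred terms drawn for event cases.
#' @param noise_terms Background preferred-term pool.
#' @param noise_pt_mean Mean number of extra background terms per case
#'   (every non-event case keeps at least one reaction).
#' @param n_background_drugs Size of the concomitant drug-name pool; every
#'   case receives at least one drug entry.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 20000,
                             seed = 1,
                             background_event_prob = 0.05,
                             drug_specs = data.frame(
                               drug_name = "drug_a",
                               exposure_prob = 0.05,
                               true_ror = 2
                             ),
                             sex_probs = c(male = 0.48, female = 0.48, missing = 0.04),
                             age_mean = 58,
                             age_sd = 17,
                             age_missing_prob = 0.05,
                             duplicate_prob = 0.10,
                             onset_model = list(family = "exponential", scale = 150),
                             partial_date_prob = 0.15,
                             event_terms = c(
                               "hyperglycaemia", "blood glucose increased",
                               "diabetes mellitus", "glucose tolerance impaired",
                               "glycosylated haemoglobin increased"
                             ),
                             noise_terms = paste0("background reaction ", sprintf("%02d", 1:30)),
                             noise_pt_mean = 1,
                             n_background_drugs = 20) {
  cfg <- list(
    n_cases = n_cases, seed = seed,
    background_event_prob = background_event_prob,
    drug_specs = tibble::as_tibble(drug_specs),
    sex_probs = sex_probs,
    age_mean = age_mean, age_sd = age_sd, age_missing_prob = age_missing_prob,
    duplicate_prob = duplicate_prob,
    onset_model = onset_model,
    partial_date_prob = partial_date_prob,
    event_terms = normalize_term(event_terms),
    noise_terms = normalize_term(noise_terms),
    noise_pt_mean = noise_pt_mean,
    n_background_drugs = n_background_drugs
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  p_in <- function(x, lo = 0, hi = 1) all(is.finite(x)) && all(x >= lo & x <= hi)
  if (!(is.numeric(cfg$n_cases) && cfg$n_cases >= 1)) {
    stop("n_cases must be a positive integer", call. = FALSE)
  }
  if (!p_in(cfg$background_event_prob) ||
      cfg$background_event_prob <= 0 || cfg$background_event_prob >= 1) {
    stop("background_event_prob must lie strictly in (0, 1)", call. = FALSE)
  }
  ds <- cfg$drug_specs
  if (!all(c("drug_name", "exposure_prob", "true_ror") %in% names(ds))) {
    stop("drug_specs needs columns drug_name, exposure_prob, true_ror", call. = FALSE)
  }
  if (!p_in(ds$exposure_prob) || any(ds$exposure_prob <= 0 | ds$exposure_prob >= 1)) {
    stop("exposure_prob values must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(ds$true_ror <= 0)) stop("true_ror must be > 0", call. = FALSE)
  if (!isTRUE(all.equal(sum(cfg$sex_probs), 1)) ||
      !all(c("male", "female", "missing") %in% names(cfg$sex_probs))) {
    stop("sex_probs must be named male/female/missing and sum to 1", call. = FALSE)
  }
  if (!p_in(c(cfg$duplicate_prob, cfg$partial_date_prob)) ||
      cfg$duplicate_prob >= 1 || cfg$partial_date_prob >= 1) {
    stop("duplicate_prob and partial_date_prob must lie in [0, 1)", call. = FALSE)
  }
  if (!cfg$onset_model$family %in% c("exponential", "weibull")) {
    stop("onset_model$family must be 'exponential' or 'weibull'", call. = FALSE)
  }
  if (!length(cfg$event_terms)) stop("event_terms must be non-empty", call. = FALSE)
  invisible(cfg)
}

#' Generate synthetic spontaneous reports
#'
#' Draws a full report set under a [synthetic_config()]: demographics,
#' per-case drug lists (focal drugs by configured exposure probabilities
#' plus a concomitant background pool), reaction preferred terms (event
#' terms for event cases, background noise terms for all), drug start dates
#' and event onset dates (possibly degraded to year-month precision), and
#' duplicate report versions for a random subset of cases. Duplicate
#' versions are strictly newer and may amend fields (a missing sex gets
#' filled, an extra reaction appears), exercising the latest-version
#' deduplication rule downstream.
#'
#' @param config A [synthetic_config()].
#' @return An `srs_reports` tibble (pre-deduplication: duplicated cases
#'   carry two version rows) with attribute `truth` recording the injected
#'   drug parameters.
#' @export
#' @examples
#' reports <- simulate_reports(synthetic_config(n_cases = 200, seed = 7))
#' nrow(reports)
simulate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, simulate_reports_impl(config))
}

simulate_reports_impl <- function(cfg) {
  n <- as.integer(cfg$n_cases)
  case_id <- sprintf("C%07d", seq_len(n))

  sex <- sample(c("male", "female", NA_character_), n, replace = TRUE,
                prob = cfg$sex_probs[c("male", "female", "missing")])
  age <- round(pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 0), 99))
  age[stats::runif(n) < cfg$age_missing_prob] <- NA

  ds <- cfg$drug_specs
  k <- nrow(ds)
  expo <- matrix(stats::rbinom(n * k, 1, rep(ds$exposure_prob, each = n)), nrow = n)
  o0 <- cfg$background_event_prob / (1 - cfg$background_event_prob)
  log_odds <- log(o0) + as.vector(expo %*% log(ds$true_ror))
  event <- stats::runif(n) < stats::plogis(log_odds)

  # drug entries: focal exposures plus >=1 concomitant background drug
  focal <- which(expo == 1, arr.ind = TRUE)
  bg_count <- 1L + stats::rpois(n, 0.5)
  bg_case <- rep.int(seq_len(n), bg_count)
  bg_pool <- paste0("background drug ", sprintf("%02d", seq_len(cfg$n_background_drugs)))
  drug_case <- c(focal[, 1], bg_case)
  drug_name <- c(ds$drug_name[focal[, 2]], sample(bg_pool, length(bg_case), replace = TRUE))
  ord <- order(drug_case)
  drug_case <- drug_case[ord]
  drug_name <- drug_name[ord]
  start_full <- as.Date("2011-01-01") +
    sample.int(2000L, length(drug_case), replace = TRUE) - 1L
  start_str <- partialize_date(start_full, cfg$partial_date_prob)
  f_case <- factor(drug_case, levels = seq_len(n))
  drugs <- split(drug_name, f_case)
  drug_starts <- split(start_str, f_case)

  # onset reference per case: earliest focal-drug start when exposed (the
  # event follows the suspect drug), else earliest drug start
  focal_flag <- c(rep(TRUE, nrow(focal)), rep(FALSE, length(bg_case)))[ord]
  min_date_by_case <- function(dates, mask) {
    d <- as.numeric(dates)
    d[!mask] <- Inf
    unname(vapply(split(d, f_case), min, numeric(1)))
  }
  any_date <- min_date_by_case(start_full, rep(TRUE, length(start_full)))
  focal_date <- min_date_by_case(start_full, focal_flag)
  index_date <- as.Date(ifelse(is.finite(focal_date), focal_date, any_date),
                        origin = "1970-01-01")

  # reactions: event PTs for event cases, noise PTs for everyone
  n_event_pt <- ifelse(event, 1L + stats::rbinom(n, 1, 0.15), 0L)
  n_noise_pt <- stats::rpois(n, cfg$noise_pt_mean)
  n_noise_pt[!event & n_noise_pt == 0L] <- 1L
  delay <- switch(cfg$onset_model$family,
    exponential = stats::rexp(n, 1 / cfg$onset_model$scale),
    weibull = stats::rweibull(n, cfg$onset_model$shape, cfg$onset_model$scale)
  )
  onset_str <- partialize_date(index_date + round(delay), cfg$partial_date_prob)

  pt_case <- c(rep.int(seq_len(n), n_event_pt), rep.int(seq_len(n), n_noise_pt))
  pt_name <- c(
    sample(cfg$event_terms, sum(n_event_pt), replace = TRUE),
    sample(cfg$noise_terms, sum(n_noise_pt), replace = TRUE)
  )
  pt_onset <- c(onset_str[rep.int(seq_len(n), n_event_pt)],
                rep("", sum(n_noise_pt)))
  ord <- order(pt_case)
  f_pt <- factor(pt_case[ord], levels = seq_len(n))
  reactions <- split(pt_name[ord], f_pt)
  reaction_onsets <- split(pt_onset[ord], f_pt)

  out <- tibble::tibble(
    source = "SYNTH",
    case_id = case_id,
    version = 1,
    sex = sex,
    age_years = age,
    age_decade = NA_integer_,
    drugs = unname(drugs),
    drug_starts = unname(drug_starts),
    reactions = unname(reactions),
    reaction_onsets = unname(reaction_onsets)
  )

  if (cfg$duplicate_prob > 0) {
    dup <- which(stats::runif(n) < cfg$duplicate_prob)
    if (length(dup)) {
      amended <- out[dup, ]
      amended$version <- 2
      filled <- sample(c("male", "female"), length(dup), replace = TRUE)
      amended$sex <- ifelse(is.na(amended$sex), filled, amended$sex)
      extra <- sample(cfg$noise_terms, length(dup), replace = TRUE)
      amended$reactions <- purrr::map2(amended$reactions, extra, c)
      amended$reaction_onsets <- purrr::map(amended$reaction_onsets, c, "")
      out <- dplyr::bind_rows(out, amended)
    }
  }
  out <- dplyr::arrange(out, .data$case_id, .data$version)
  out <- as_srs_reports(out)
  attr(out, "truth") <- ds
  out
}

partialize_date <- function(dates, partial_prob) {
  s <- format(dates, "%Y-%m-%d")
  drop <- stats::runif(length(dates)) < partial_prob
  s[drop] <- format(dates[drop], "%Y-%m")
  s
}

#' Write reports as FAERS-style or JADER-style tables
#'
#' Serializes an `srs_reports` tibble into the three-table layout of the
#' chosen dialect, producing files readable by [read_faers_tables()] /
#' [read_jader_tables()]. The round trip is lossless for every field the
#' dialect can represent; under the JADER dialect ages are down-coded to
#' decade strings (37 becomes `"30s"`), which is exactly the precision the
#' real archive offers.
#'
#' @param reports An `srs_reports` tibble.
#' @param dialect `"FAERS"`, `"JADER"`, or an `srs_dialect` object.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the three file paths (demo, drug, reac).
#' @export
write_srs_tables <- function(reports, dialect = "FAERS", out_dir) {
  if (is.character(dialect)) {
    dialect <- switch(match.arg(dialect, c("FAERS", "JADER")),
      FAERS = faers_dialect(), JADER = jader_dialect()
    )
  }
  stopifnot(inherits(dialect, "srs_dialect"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map <- dialect$col_map
  inv_sex <- stats::setNames(names(dialect$sex_map), dialect$sex_map)

  demo <- tibble::tibble(a = reports$case_id, b = format_version(reports$version))
  names(demo) <- c(map$demo[["case_id"]], map$demo[["version"]])
  demo[[map$demo[["sex"]]]] <- ifelse(is.na(reports$sex), "", inv_sex[reports$sex])
  if (dialect$age_coding == "years") {
    demo[[map$demo[["age"]]]] <- ifelse(is.na(reports$age_years), "",
                                        format(reports$age_years, trim = TRUE))
    if ("age_unit" %in% names(map$demo)) {
      demo[[map$demo[["age_unit"]]]] <- ifelse(is.na(reports$age_years), "", "YR")
    }
  } else {
    dec <- ifelse(!is.na(reports$age_decade), reports$age_decade,
                  floor(reports$age_years / 10) * 10)
    demo[[map$demo[["age"]]]] <- ifelse(is.na(dec), "", paste0(dec, "s"))
  }

  unroll <- function(value_col, date_col, value_name, date_name, role) {
    len <- lengths(reports[[value_col]])
    out <- tibble::tibble(
      a = rep.int(reports$case_id, len),
      b = format_version(rep.int(reports$version, len))
    )
    names(out) <- c(map[[role]][["case_id"]], map[[role]][["version"]])
    out[[value_name]] <- unlist(reports[[value_col]], use.names = FALSE)
    out[[date_name]] <- iso_to_dialect_date(
      unlist(reports[[date_col]], use.names = FALSE), dialect$date_format
    )
    out
  }
  drug <- unroll("drugs", "drug_starts",
                 map$drug[["drug_name"]], map$drug[["start_date"]], "drug")
  reac <- unroll("reactions", "reaction_onsets",
                 map$reac[["preferred_term"]], map$reac[["onset_date"]], "reac")

  ext <- if (dialect$delim == ",") ".csv" else ".txt"
  prefix <- if (dialect$source == "FAERS") c("DEMO", "DRUG", "REAC") else c("demo", "drug", "reac")
  paths <- file.path(out_dir, paste0(prefix, ext))
  names(paths) <- c("demo", "drug", "reac")
  readr::write_delim(demo, paths[["demo"]], delim = dialect$delim)
  readr::write_delim(drug, paths[["drug"]], delim = dialect$delim)
  readr::write_delim(reac, paths[["reac"]], delim = dialect$delim)
  paths
}

format_version <- function(v) {
  ifelse(v == round(v), format(as.integer(round(v))), format(v, trim = TRUE))
}
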