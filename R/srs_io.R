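#' Read FAERS-style or JADER-style report tables
#'
#' Reads the three table roles of a spontaneous reporting system extract —
#' demographics, drugs, reactions — into canonical per-role tibbles without
#' joining them (see [assemble_reports()] for that step). Values are kept as
#' close to verbatim as the canonical schema allows: ages stay strings until
#' assembly (JADER codes them as decades, FAERS as numbers with a unit
#' column), while dates are re-expressed as partial ISO strings, preserving
#' whatever precision the file had.
#'
#' Rows that cannot be carried forward (empty case identifier) are never
#' silently dropped: they are collected in the `rejects` element with a
#' reason, and their count is reported.
#'
#' @param demo_path,drug_path,reac_path Paths to the three tables.
#' @param dialect An [faers_dialect()] / [jader_dialect()] description.
#' @return A list of class `srs_raw` with elements `demo`, `drug`, `reac`
#'   (canonical tibbles, each with a `table_origin` column), `rejects`
#'   (tibble with `table_origin`, `case_id`, `reason`), `source` and
#'   `dialect`.
#' @export
read_faers_tables <- function(demo_path, drug_path, reac_path,
                              dialect = faers_dialect()) {
  read_srs_tables(demo_path, drug_path, reac_path, dialect)
}

#' @rdname read_faers_tables
#' @export
read_jader_tables <- function(demo_path, drug_path, reac_path,
                              dialect = jader_dialect()) {
  read_srs_tables(demo_path, drug_path, reac_path, dialect)
}

read_srs_tables <- function(demo_path, drug_path, reac_path, dialect) {
  stopifnot(inherits(dialect, "srs_dialect"))
  paths <- c(demo = unname(demo_path), drug = unname(drug_path),
             reac = unname(reac_path))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input table(s) not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  parts <- lapply(names(paths), function(role) {
    read_one_table(paths[[role]], role, dialect)
  })
  names(parts) <- names(paths)
  rejects <- dplyr::bind_rows(lapply(parts, attr, "rejects"))
  if (nrow(rejects)) {
    message(nrow(rejects), " row(s) rejected at read; see $rejects")
  }
  structure(
    list(
      demo = parts$demo, drug = parts$drug, reac = parts$reac,
      rejects = rejects, source = dialect$source, dialect = dialect
    ),
    class = "srs_raw"
  )
}

read_one_table <- function(path, role, dialect) {
  map <- dialect$col_map[[role]]
  raw <- readr::read_delim(
    path,
    delim = dialect$delim,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = dialect$encoding),
    na = character(),
    progress = FALSE,
    show_col_types = FALSE
  )
  absent <- setdiff(unname(map), names(raw))
  if (length(absent)) {
    stop(
      "table '", role, "' (", path, ") lacks mapped column(s): ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    case_id = trimws(raw[[map[["case_id"]]]]),
    version = if ("version" %in% names(map)) {
      suppressWarnings(as.numeric(raw[[map[["version"]]]]))
    } else {
      1
    }
  )
  out$version[is.na(out$version)] <- 1
  if (role == "demo") {
    sex_raw <- trimws(raw[[map[["sex"]]]])
    out$sex <- unname(dialect$sex_map[sex_raw])
    out$age_value <- trimws(raw[[map[["age"]]]])
    out$age_unit <- if ("age_unit" %in% names(map)) {
      trimws(raw[[map[["age_unit"]]]])
    } else {
      NA_character_
    }
  } else if (role == "drug") {
    out$drug_name <- normalize_term(raw[[map[["drug_name"]]]])
    out$start_date <- dialect_date_to_iso(raw[[map[["start_date"]]]], dialect$date_format)
  } else {
    out$preferred_term <- trimws(raw[[map[["preferred_term"]]]])
    out$onset_date <- dialect_date_to_iso(raw[[map[["onset_date"]]]], dialect$date_format)
  }
  out$table_origin <- role
  bad <- out$case_id == "" | is.na(out$case_id)
  rejects <- tibble::tibble(
    table_origin = character(), case_id = character(), reason = character()
  )
  if (any(bad)) {
    rejects <- tibble::tibble(
      table_origin = role,
      case_id = out$case_id[bad],
      reason = "empty_case_id"
    )
    out <- out[!bad, ]
  }
  attr(out, "rejects") <- rejects
  out
}

#' Assemble canonical reports from raw per-role rows
#'
#' Joins demographics, drug and reaction rows on (case identifier, report
#' version) into one report row per version, with drugs and reactions as
#' list-columns. Demographics come from the demo row only; drug or reaction
#' rows whose key has no demo row are set aside as rejects, never silently
#' dropped, and no demo row is ever invented or lost.
#'
#' Age parsing happens here: under `"years"` coding the verbatim value is
#' converted to years using the unit column when one was mapped (`YR`,
#' `DEC`, `MON`, `WK`, `DY`; a missing unit is treated as years and counted
#' in the QC summary), while `"decades"` coding produces the decade lower
#' edge (`"30s"` or `30` becomes 30).
#'
#' @param raw An `srs_raw` list from [read_faers_tables()] /
#'   [read_jader_tables()].
#' @return A tibble of class `srs_reports`, one row per (case_id, version),
#'   sorted, with attributes `rejects` (orphan drug/reac rows) and `qc`
#'   (named counts).
#' @export
assemble_reports <- function(raw) {
  stopifnot(inherits(raw, "srs_raw"))
  demo <- dplyr::distinct(raw$demo, .data$case_id, .data$version, .keep_all = TRUE)
  keys <- dplyr::select(demo, "case_id", "version")

  attach_role <- function(tbl, value_col, date_col) {
    known <- dplyr::semi_join(tbl, keys, by = c("case_id", "version"))
    orphan <- dplyr::anti_join(tbl, keys, by = c("case_id", "version"))
    grouped <- known |>
      dplyr::group_by(.data$case_id, .data$version) |>
      dplyr::summarise(
        values = list(.data[[value_col]]),
        dates = list(.data[[date_col]]),
        .groups = "drop"
      )
    list(grouped = grouped, orphan = orphan)
  }

  drugs <- attach_role(raw$drug, "drug_name", "start_date")
  reacs <- attach_role(raw$reac, "preferred_term", "onset_date")

  age <- parse_age(demo$age_value, demo$age_unit, raw$dialect$age_coding)

  out <- tibble::tibble(
    source = raw$source,
    case_id = demo$case_id,
    version = demo$version,
    sex = demo$sex,
    age_years = age$age_years,
    age_decade = age$age_decade
  )
  out <- out |>
    dplyr::left_join(
      dplyr::rename(drugs$grouped, drugs = "values", drug_starts = "dates"),
      by = c("case_id", "version")
    ) |>
    dplyr::left_join(
      dplyr::rename(reacs$grouped, reactions = "values", reaction_onsets = "dates"),
      by = c("case_id", "version")
    )
  for (col in c("drugs", "drug_starts", "reactions", "reaction_onsets")) {
    out[[col]] <- purrr::map(out[[col]], ~ .x %||% character(0))
  }
  out <- dplyr::arrange(out, .data$case_id, .data$version)

  rejects <- dplyr::bind_rows(
    dplyr::mutate(drugs$orphan, reason = "no_matching_demo_row"),
    dplyr::mutate(reacs$orphan, reason = "no_matching_demo_row")
  )
  out <- as_srs_reports(out)
  attr(out, "rejects") <- rejects
  attr(out, "qc") <- c(
    demo_rows = nrow(demo),
    orphan_drug_rows = nrow(drugs$orphan),
    orphan_reac_rows = nrow(reacs$orphan),
    age_unit_assumed_years = age$assumed_years
  )
  out
}

parse_age <- function(age_value, age_unit, age_coding) {
  n <- length(age_value)
  if (age_coding == "years") {
    v <- suppressWarnings(as.numeric(age_value))
    unit <- toupper(ifelse(is.na(age_unit), "", age_unit))
    factor <- c(
      YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18, DY = 1 / 365.25, HR = 1 / 8766
    )
    f <- unname(factor[unit])
    assumed <- !is.na(v) & (unit == "" | is.na(f))
    f[is.na(f)] <- 1
    f[unit == ""] <- 1
    years <- v * f
    years[!is.na(years) & years < 0] <- NA
    list(
      age_years = years,
      age_decade = rep(NA_integer_, n),
      assumed_years = sum(assumed)
    )
  } else {
    num <- stringr::str_match(age_value, "^(\\d{1,3})")[, 2]
    v <- suppressWarnings(as.integer(num))
    dec <- as.integer(pmin(floor(v / 10) * 10, 100L))
    list(
      age_years = rep(NA_real_, n),
      age_decade = dec,
      assumed_years = 0L
    )
  }
}

#' Write and re-read screening results
#'
#' Writes one delimited row per drug-stratum result with the four cell
#' counts, the ROR and its Wald 95% CI at full precision, the signal flag
#' and the Fisher exact p-value, plus rounded display columns matching the
#' conventional presentation (ROR to 2 decimals, CI bounds to 3, half-up).
#'
#' @param results A tibble from [ror_screen()].
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  core <- c(
    "source", "drug", "event_set", "stratum", "n11", "n12", "n21", "n22",
    "ror", "ci_low", "ci_high", "signal", "fisher_p"
  )
  stopifnot(all(core %in% names(results)))
  out <- tibble::as_tibble(results)[, core]
  fmt <- function(x, d) ifelse(is.na(x), NA_character_,
                               formatC(round_half_up(x, d), format = "f", digits = d))
  out$ror_display <- fmt(out$ror, 2)
  out$ci_low_display <- fmt(out$ci_low, 3)
  out$ci_high_display <- fmt(out$ci_high, 3)
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  writer(out, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  reader(
    path,
    col_types = readr::cols(
      source = "c", drug = "c", event_set = "c", stratum = "c",
      n11 = "i", n12 = "i", n21 = "i", n22 = "i",
      ror = "d", ci_low = "d", ci_high = "d", signal = "l", fisher_p = "d",
      ror_display = "c", ci_low_display = "c", ci_high_display = "c"
    ),
    progress = FALSE
  )
}
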