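#' Table dialects for spontaneous reporting system extracts
#'
#' Real FAERS and JADER downloads differ in delimiter, column naming, sex
#' and age coding, and date formats — and the column layouts drift across
#' quarters. Rather than hard-coding one layout, readers and writers are
#' driven by a dialect description: which physical column maps to each
#' canonical field, how dates are written, and how age is coded (years for
#' FAERS, 10-year decade codes for JADER).
#'
#' The defaults describe the ASCII fixture layouts used throughout the
#' package: FAERS-style `$`-delimited tables with `YYYYMMDD` compact dates,
#' and JADER-style comma-delimited tables with `YYYY/MM/DD` dates and decade
#' age strings such as `"30s"`. Real JADER files are Shift-JIS encoded and
#' use Japanese column headers; point `encoding` and `col_map` at them to
#' adapt.
#'
#' @param delim Field delimiter.
#' @param encoding Character encoding of the files.
#' @param col_map Named list with entries `demo`, `drug`, `reac`; each a
#'   named character vector mapping canonical field names (`case_id`,
#'   `version`, `sex`, `age`, `age_unit`, `drug_name`, `start_date`,
#'   `preferred_term`, `onset_date`) to physical column names. `version` and
#'   `age_unit` may be omitted (version defaults to 1, ages are then taken
#'   in the dialect's native coding).
#' @param sex_map Named character vector mapping raw sex codes to
#'   `"male"`/`"female"`; unmapped values become missing.
#' @param age_coding `"years"` or `"decades"`.
#' @param date_format `"ymd_compact"` (`20150302`, `201503`, `2015`) or
#'   `"ymd_slash"` (`2015/03/02`, `2015/03`, `2015`).
#' @return A list of class `srs_dialect`.
#' @export
#' @examples
#' faers_dialect()$col_map$demo
faers_dialect <- function(delim = "$",
                          encoding = "UTF-8",
                          col_map = list(
                            demo = c(case_id = "caseid", version = "caseversion",
                                     sex = "sex", age = "age", age_unit = "age_cod"),
                            drug = c(case_id = "caseid", version = "caseversion",
                                     drug_name = "drugname", start_date = "start_dt"),
                            reac = c(case_id = "caseid", version = "caseversion",
                                     preferred_term = "pt", onset_date = "onset_dt")
                          ),
                          sex_map = c(M = "male", F = "female"),
                          age_coding = "years",
                          date_format = "ymd_compact") {
  new_dialect("FAERS", delim, encoding, col_map, sex_map, age_coding, date_format)
}

#' @rdname faers_dialect
#' @export
jader_dialect <- function(delim = ",",
                          encoding = "UTF-8",
                          col_map = list(
                            demo = c(case_id = "case_number", version = "report_order",
                                     sex = "sex", age = "age"),
                            drug = c(case_id = "case_number", version = "report_order",
                                     drug_name = "drug_name", start_date = "start_date"),
                            reac = c(case_id = "case_number", version = "report_order",
                                     preferred_term = "adverse_event", onset_date = "onset_date")
                          ),
                          sex_map = c(male = "male", female = "female"),
                          age_coding = "decades",
                          date_format = "ymd_slash") {
  new_dialect("JADER", delim, encoding, col_map, sex_map, age_coding, date_format)
}

new_dialect <- function(source, delim, encoding, col_map, sex_map,
                        age_coding, date_format) {
  stopifnot(
    all(c("demo", "drug", "reac") %in% names(col_map)),
    age_coding %in% c("years", "decades"),
    date_format %in% c("ymd_compact", "ymd_slash")
  )
  structure(
    list(
      source = source, delim = delim, encoding = encoding, col_map = col_map,
      sex_map = sex_map, age_coding = age_coding, date_format = date_format
    ),
    class = "srs_dialect"
  )
}

# dialect date string -> canonical partial ISO ("2015-03-02" / "2015-03" / "2015")
dialect_date_to_iso <- function(x, date_format) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  if (date_format == "ymd_compact") {
    out <- rep("", length(x))
    out[grepl("^\\d{4}$", x)] <- x[grepl("^\\d{4}$", x)]
    i <- grepl("^\\d{6}$", x)
    out[i] <- paste0(substr(x[i], 1, 4), "-", substr(x[i], 5, 6))
    i <- grepl("^\\d{8}$", x)
    out[i] <- paste0(substr(x[i], 1, 4), "-", substr(x[i], 5, 6), "-", substr(x[i], 7, 8))
    out
  } else {
    gsub("/", "-", x)
  }
}

iso_to_dialect_date <- function(x, date_format) {
  x[is.na(x)] <- ""
  if (date_format == "ymd_compact") gsub("-", "", x) else gsub("-", "/", x)
}
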