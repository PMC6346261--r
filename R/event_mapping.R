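#' Define an outcome event set of MedDRA preferred terms
#'
#' The outcome of interest is defined by a set of preferred terms (PTs)
#' standing in for a Standardised MedDRA Query: for impaired glucose
#' metabolism that is SMQ 20000041 ("hyperglycaemia/new onset diabetes
#' mellitus", 113 PTs). MedDRA content is licensed, so the PT list itself is
#' always a user input; a synthetic stand-in list ships with the package for
#' testing (see `system.file("extdata",
#' "impaired_glucose_metabolism_synthetic_terms.txt", package =
#' "rorscreen")`).
#'
#' Terms are normalized (trim, collapse whitespace, case-fold) and
#' deduplicated; matching everywhere is exact-string on the normalized form.
#'
#' @param terms Character vector of preferred terms.
#' @param name Event-set name, recorded in outputs.
#' @param smq_id Optional SMQ identifier, recorded in outputs.
#' @return A list of class `term_set` with elements `name`, `smq_id`,
#'   `terms` (sorted, normalized, unique).
#' @export
#' @examples
#' term_set(c("Hyperglycaemia", "hyperglycaemia", "Diabetes mellitus"))
term_set <- function(terms, name = "event set", smq_id = NULL) {
  terms <- unique(normalize_term(terms))
  terms <- terms[terms != "" & !is.na(terms)]
  if (!length(terms)) stop("term set is empty", call. = FALSE)
  structure(
    list(name = name, smq_id = smq_id, terms = sort(terms)),
    class = "term_set"
  )
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf(
    "<term_set '%s'%s: %d preferred terms>\n",
    x$name, if (is.null(x$smq_id)) "" else paste0(" (SMQ ", x$smq_id, ")"),
    length(x$terms)
  ))
  invisible(x)
}

#' Read a preferred-term list file
#'
#' One preferred term per line; blank lines are skipped. Optional header
#' comment lines of the form `# name: ...` and `# smq_id: ...` carry the
#' event-set metadata.
#'
#' @param path Path to the term-list file.
#' @return A [term_set()]; its size is reported via `message()`.
#' @export
read_term_set <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta <- stringr::str_match(lines, "^#\\s*(name|smq_id)\\s*:\\s*(.+?)\\s*$")
  name <- meta[which(meta[, 2] == "name")[1], 3]
  smq_id <- meta[which(meta[, 2] == "smq_id")[1], 3]
  terms <- lines[!stringr::str_starts(lines, "#")]
  terms <- terms[stringr::str_squish(terms) != ""]
  if (!length(terms)) stop("term-set file has no terms: ", path, call. = FALSE)
  ts <- term_set(
    terms,
    name = if (is.na(name)) basename(path) else name,
    smq_id = if (is.na(smq_id)) NULL else smq_id
  )
  message("loaded term set '", ts$name, "': ", length(ts$terms), " preferred terms")
  ts
}

#' Event-set membership per report
#'
#' A report belongs to the outcome event set iff at least one of its
#' reaction preferred terms (normalized) is in the term set. Counting is at
#' case level: a report with three matching terms is one event case, so the
#' contingency-table cells below always sum to the report count.
#'
#' `has_event()` returns the bare logical vector (the fast path used by the
#' screen); `match_events()` additionally reports which terms matched.
#'
#' @param reports An `srs_reports` tibble.
#' @param terms A [term_set()].
#' @return `has_event()`: logical vector along `reports`. `match_events()`:
#'   a tibble with `case_id`, `has_event`, and a `matched_terms`
#'   list-column.
#' @export
has_event <- function(reports, terms) {
  stopifnot(is.data.frame(reports), inherits(terms, "term_set"))
  pts <- unlist(reports$reactions, use.names = FALSE)
  if (!length(pts)) return(rep(FALSE, nrow(reports)))
  hit <- normalize_term(pts) %in% terms$terms
  idx <- rep.int(seq_len(nrow(reports)), lengths(reports$reactions))
  out <- rep(FALSE, nrow(reports))
  out[unique(idx[hit])] <- TRUE
  out
}

#' @rdname has_event
#' @export
match_events <- function(reports, terms) {
  stopifnot(is.data.frame(reports), inherits(terms, "term_set"))
  matched <- purrr::map(reports$reactions, function(p) {
    norm <- normalize_term(p)
    unique(norm[norm %in% terms$terms])
  })
  tibble::tibble(
    case_id = reports$case_id,
    has_event = lengths(matched) > 0,
    matched_terms = matched
  )
}
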