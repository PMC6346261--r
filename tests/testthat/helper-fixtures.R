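# Row-wise report builder for hand-crafted fixtures.
report_row <- function(case_id, version = 1, sex = "male", age_years = 50,
                       age_decade = NA_integer_, source = "FAERS",
                       drugs = character(0), drug_starts = NULL,
                       reactions = character(0), reaction_onsets = NULL) {
  drug_starts <- drug_starts %||% rep("", length(drugs))
  reaction_onsets <- reaction_onsets %||% rep("", length(reactions))
  tibble::tibble(
    source = source, case_id = case_id, version = version, sex = sex,
    age_years = age_years, age_decade = as.integer(age_decade),
    drugs = list(drugs),
    drug_starts = list(drug_starts),
    reactions = list(reactions),
    reaction_onsets = list(reaction_onsets)
  )
}

bind_reports <- function(...) {
  rorscreen:::as_srs_reports(dplyr::bind_rows(...))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

glucose_terms <- function() {
  term_set(
    c("hyperglycaemia", "blood glucose increased", "diabetes mellitus",
      "glucose tolerance impaired", "glycosylated haemoglobin increased"),
    name = "impaired glucose metabolism"
  )
}

# The published 2x2 counts bundled with the package, with cells derived.
published_counts <- function() {
  d <- readr::read_csv(
    system.file("extdata", "bcr_abl_glucose_counts.csv", package = "rorscreen"),
    show_col_types = FALSE
  )
  dplyr::mutate(d,
    n11 = n_event_drug,
    n12 = n_drug - n_event_drug,
    n21 = n_event_nodrug,
    n22 = n_nodrug - n_event_nodrug
  )
}

# List-column equality ignoring names attribute noise.
expect_listcol_equal <- function(a, b) {
  expect_true(all(mapply(function(x, y) identical(unname(x), unname(y)), a, b)))
}
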