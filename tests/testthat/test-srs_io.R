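write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("FAERS-style tables read row for row with missingness preserved", {
  demo <- write_lines_tmp(c(
    "caseid$caseversion$sex$age$age_cod",
    "C1$1$M$45$YR",
    "C2$1$$61$YR",
    "C3$2$F$$"
  ))
  drug <- write_lines_tmp(c("caseid$caseversion$drugname$start_dt",
                            "C1$1$Nilotinib$20150102"))
  reac <- write_lines_tmp(c("caseid$caseversion$pt$onset_dt",
                            "C1$1$Hyperglycaemia$201503"))
  raw <- read_faers_tables(demo, drug, reac)
  expect_equal(nrow(raw$demo), 3)
  expect_true(all(raw$demo$table_origin == "demo"))
  expect_equal(raw$demo$sex, c("male", NA, "female"))
  expect_equal(raw$demo$age_value, c("45", "61", ""))
  expect_equal(raw$drug$drug_name, "nilotinib")
  expect_equal(raw$drug$start_date, "2015-01-02")
  # year-month onset survives as a partial date
  expect_equal(raw$reac$onset_date, "2015-03")
})

test_that("JADER-style decade age strings are preserved verbatim at read", {
  demo <- write_lines_tmp(c("case_number,report_order,sex,age",
                            "J1,1,male,30s"))
  drug <- write_lines_tmp(c("case_number,report_order,drug_name,start_date",
                            "J1,1,nilotinib,2015/01/02"))
  reac <- write_lines_tmp(c("case_number,report_order,adverse_event,onset_date",
                            "J1,1,hyperglycaemia,2015/03"))
  raw <- read_jader_tables(demo, drug, reac)
  expect_equal(raw$demo$age_value, "30s")
  expect_equal(raw$reac$onset_date, "2015-03")
  rep <- assemble_reports(raw)
  expect_equal(rep$age_decade, 30L)
  p <- parse_partial_date(rep$reaction_onsets[[1]])
  expect_equal(p$month, 3L)
  expect_true(is.na(p$day))
})

test_that("missing files and unmapped columns are fatal", {
  demo <- write_lines_tmp(c("caseid$caseversion$sex$age$age_cod", "C1$1$M$45$YR"))
  expect_error(read_faers_tables("no/such/file", demo, demo), "not found")
  bad <- write_lines_tmp(c("wrongname$caseversion$sex$age$age_cod", "C1$1$M$45$YR"))
  expect_error(read_faers_tables(bad, demo, demo), "caseid")
})

test_that("assembly joins roles by key and logs orphans instead of dropping", {
  demo <- write_lines_tmp(c("caseid$caseversion$sex$age$age_cod", "C1$1$M$45$YR"))
  drug <- write_lines_tmp(c("caseid$caseversion$drugname$start_dt",
                            "C1$1$imatinib$20140101", "C1$1$nilotinib$20150101"))
  reac <- write_lines_tmp(c("caseid$caseversion$pt$onset_dt",
                            "C1$1$headache$", "C9$1$nausea$"))
  rep <- assemble_reports(read_faers_tables(demo, drug, reac))
  expect_equal(nrow(rep), 1)
  expect_equal(rep$drugs[[1]], c("imatinib", "nilotinib"))
  expect_equal(rep$reactions[[1]], "headache")
  rejects <- attr(rep, "rejects")
  expect_equal(nrow(rejects), 1)
  expect_equal(rejects$case_id, "C9")
  expect_equal(rejects$reason, "no_matching_demo_row")
})

test_that("round trips through both dialect writers are lossless", {
  r <- simulate_reports(synthetic_config(n_cases = 100, seed = 7))

  fd <- withr::local_tempdir()
  paths <- write_srs_tables(r, "FAERS", fd)
  back <- assemble_reports(read_faers_tables(paths["demo"], paths["drug"], paths["reac"]))
  expect_equal(nrow(back), nrow(r))
  expect_equal(back$case_id, r$case_id)
  expect_equal(back$version, r$version)
  expect_equal(back$sex, r$sex)
  expect_equal(back$age_years, as.numeric(r$age_years))
  for (col in c("drugs", "drug_starts", "reactions", "reaction_onsets")) {
    expect_listcol_equal(back[[col]], r[[col]])
  }

  # JADER represents age only at decade precision; everything else survives
  jd <- withr::local_tempdir()
  jp <- write_srs_tables(r[1:50, ], "JADER", jd)
  jback <- assemble_reports(read_jader_tables(jp["demo"], jp["drug"], jp["reac"]))
  expect_equal(jback$age_decade,
               as.integer(floor(r$age_years[1:50] / 10) * 10))
  for (col in c("drugs", "drug_starts", "reactions", "reaction_onsets")) {
    expect_listcol_equal(jback[[col]], r[[col]][1:50])
  }
})

test_that("assembled report count equals distinct (case, version) pairs", {
  r <- simulate_reports(synthetic_config(n_cases = 200, seed = 11,
                                         duplicate_prob = 0.3))
  td <- withr::local_tempdir()
  paths <- write_srs_tables(r, "FAERS", td)
  raw <- read_faers_tables(paths["demo"], paths["drug"], paths["reac"])
  rep <- assemble_reports(raw)
  # brute-force recount from the raw demo rows
  expect_equal(nrow(rep),
               nrow(unique(data.frame(raw$demo$case_id, raw$demo$version))))
})

test_that("results files round trip with display columns", {
  r <- simulate_reports(synthetic_config(n_cases = 2000, seed = 5)) |>
    deduplicate_reports() |>
    apply_eligibility()
  res <- ror_screen(r, "drug_a", glucose_terms())
  f <- withr::local_tempfile(fileext = ".csv")

  write_results(res[0, ], f)
  expect_equal(nrow(read_results(f)), 0)

  write_results(res[1, ], f)
  one <- read_results(f)
  expect_equal(ncol(one), 16)  # 13 core + 3 display columns
  expect_false(anyNA(one[, c("source", "drug", "stratum", "n11", "n22")]))

  write_results(res, f)
  back <- read_results(f)
  expect_equal(back$ror, res$ror)
  expect_equal(back$ci_low, res$ci_low)
  expect_equal(back$fisher_p, res$fisher_p)
  expect_equal(back$signal, res$signal)
  expect_equal(back$ror_display,
               formatC(round_half_up(res$ror, 2), format = "f", digits = 2))
})
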