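test_that("deduplication keeps the latest report version of each case", {
  r <- bind_reports(
    report_row("C1", version = 1, sex = "male"),
    report_row("C1", version = 3, sex = "female"),
    report_row("C2", version = 1)
  )
  d <- deduplicate_reports(r)
  expect_equal(nrow(d), 2)
  expect_equal(d$sex[d$case_id == "C1"], "female")

  # all-distinct input passes through unchanged as a set
  distinct <- bind_reports(report_row("B2"), report_row("A1"), report_row("C3"))
  expect_equal(sort(deduplicate_reports(distinct)$case_id),
               sort(distinct$case_id))

  # idempotence
  expect_identical(as.data.frame(deduplicate_reports(d)), as.data.frame(d))
})

test_that("deduplicated size equals the brute-force distinct-case count", {
  r <- simulate_reports(synthetic_config(n_cases = 10000, seed = 21,
                                         duplicate_prob = 0.2))
  d <- deduplicate_reports(r)
  expect_equal(nrow(d), length(unique(r$case_id)))
  # and every retained row carries its case's maximal version
  max_v <- tapply(r$version, r$case_id, max)
  expect_equal(d$version, as.vector(max_v[d$case_id]))
})

test_that("eligibility applies the complete-demographics and age rules", {
  r <- bind_reports(
    report_row("C1", age_years = 20),            # boundary: excluded (> 20 strict)
    report_row("C2", age_years = 20.5),          # included
    report_row("C3", age_years = 21, sex = NA),  # missing sex: excluded
    report_row("C4", age_years = NA),            # missing age: excluded
    report_row("C5", age_years = NA, age_decade = 20, source = "JADER"),  # 20s decade: included
    report_row("C6", age_years = NA, age_decade = 10, source = "JADER")   # 10s decade: excluded
  )
  e <- apply_eligibility(r)
  expect_equal(e$case_id, c("C2", "C5"))
  qc <- attr(e, "qc")
  expect_equal(unname(qc["excluded_missing_sex"]), 1L)
  expect_equal(unname(qc["excluded_missing_age"]), 1L)
  expect_equal(unname(qc["excluded_age_bound"]), 2L)

  # sensitivity switch: >= at the year-valued boundary
  incl <- apply_eligibility(r, eligibility_config(faers_inclusive_boundary = TRUE))
  expect_true("C1" %in% incl$case_id)

  # all-reports mode bypasses every filter
  all_mode <- apply_eligibility(r, eligibility_config(all_reports_mode = TRUE))
  attr(all_mode, "qc") <- NULL
  expect_equal(as.data.frame(all_mode), as.data.frame(r))
})

test_that("eligibility matches an independent recount on synthetic data", {
  r <- deduplicate_reports(simulate_reports(synthetic_config(n_cases = 5000, seed = 8)))
  e <- apply_eligibility(r)
  manual <- !is.na(r$sex) & !is.na(r$age_years) & r$age_years > 20
  expect_equal(nrow(e), sum(manual))
  expect_equal(e$case_id, r$case_id[manual])
  expect_true(nrow(e) <= nrow(r))
})

test_that("age bands follow 10-year floors and compose into the two groups", {
  r <- bind_reports(
    report_row("C1", age_years = 37),
    report_row("C2", age_years = 70),
    report_row("C3", age_years = 104),
    report_row("C4", age_years = NA, age_decade = 40, source = "JADER")
  )
  expect_equal(age_band(r), c("30s", "70s", "100s", "40s"))
  expect_equal(age_group(r), c("20-60s", "70-90s", NA, "20-60s"))

  ages <- sample(21:99, 1000, replace = TRUE)
  rr <- bind_reports(lapply(seq_along(ages), function(i) {
    report_row(sprintf("A%04d", i), age_years = ages[i])
  }))
  expect_equal(age_band(rr), paste0(floor(ages / 10) * 10, "s"))

  # the two groups partition the eligible adult bands below 100
  g <- age_group(rr)
  expect_true(all(g %in% c("20-60s", "70-90s")))
  in_young <- floor(ages / 10) * 10 <= 60
  expect_equal(g == "20-60s", in_young)
})
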