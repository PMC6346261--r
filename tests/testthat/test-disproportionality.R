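test_that("each report lands in exactly one contingency cell", {
  ts <- glucose_terms()
  r <- bind_reports(
    report_row("C1", drugs = "nilotinib", reactions = "hyperglycaemia"),
    report_row("C2", drugs = "nilotinib", reactions = "headache"),
    report_row("C3", drugs = "imatinib", reactions = "hyperglycaemia"),
    report_row("C4", drugs = "imatinib", reactions = "nausea")
  )
  tab <- contingency_table(r, "nilotinib", ts)
  expect_equal(unlist(tab[, c("n11", "n12", "n21", "n22")]),
               c(n11 = 1, n12 = 1, n21 = 1, n22 = 1))
  expect_equal(sum(tab$n11, tab$n12, tab$n21, tab$n22), nrow(r))

  # a stratum no report satisfies gives an all-zero table
  female_only <- bind_reports(report_row("C9", sex = "female",
                                         drugs = "nilotinib",
                                         reactions = "hyperglycaemia"))
  zero <- contingency_table(female_only, "nilotinib", ts,
                            stratum = stratum_spec(sex = "male"))
  expect_equal(sum(zero$n11, zero$n12, zero$n21, zero$n22), 0)
})

test_that("contingency cells equal a brute-force recount at scale", {
  ts <- glucose_terms()
  r <- simulate_reports(synthetic_config(n_cases = 20000, seed = 31)) |>
    deduplicate_reports() |>
    apply_eligibility()
  stratum <- stratum_spec(sex = "male")
  tab <- contingency_table(r, "drug_a", ts, stratum = stratum)

  # independent recount with a plain loop
  cells <- c(n11 = 0, n12 = 0, n21 = 0, n22 = 0)
  for (i in seq_len(nrow(r))) {
    if (is.na(r$sex[i]) || r$sex[i] != "male") next
    ex <- "drug_a" %in% r$drugs[[i]]
    ev <- any(tolower(r$reactions[[i]]) %in% ts$terms)
    cell <- if (ex && ev) "n11" else if (ex) "n12" else if (ev) "n21" else "n22"
    cells[cell] <- cells[cell] + 1
  }
  expect_equal(unlist(tab[, names(cells)]), cells)
})

test_that("reporting odds ratios match published values from printed counts", {
  # overall nilotinib, FAERS extract
  expect_equal(round_half_up(ror_ci(514, 4608, 176446, 1994427)$ror, 2), 1.26)
  # overall nilotinib, JADER extract
  expect_equal(round_half_up(ror_ci(93, 1265, 20046, 360588)$ror, 2), 1.32)
  # male nilotinib, JADER extract
  expect_equal(round_half_up(ror_ci(60, 775, 10370, 183372)$ror, 2), 1.37)
})

test_that("proportional tables give a ROR of exactly one", {
  tab <- ror_ci(20, 40, 100, 200)
  expect_identical(tab$ror, 1)
  expect_true(tab$ci_low < 1 && tab$ci_high > 1)
})

test_that("zero cells yield undefined estimates unless Haldane-corrected", {
  z <- ror_ci(0, 41, 7162, 150239)
  expect_true(is.na(z$ror) && is.na(z$ci_low) && is.na(z$ci_high))
  expect_equal(z$reason, "zero_cell")
  expect_false(detect_signal(z))
  h <- ror_ci(0, 41, 7162, 150239, haldane = TRUE)
  expect_false(is.na(h$ror))
})

test_that("the estimator agrees with the cross-product oracle", {
  set.seed(42)
  n <- matrix(sample(1:500, 4000, replace = TRUE), ncol = 4)
  est <- ror_ci(n[, 1], n[, 2], n[, 3], n[, 4])
  oracle <- (n[, 1] * n[, 4]) / (n[, 2] * n[, 3])
  expect_lt(max(abs(est$ror / oracle - 1)), 1e-12)
  # bounds bracket the point estimate
  expect_true(all(est$ci_low <= est$ror & est$ror <= est$ci_high))
})

test_that("CI width shrinks as cells scale; point estimate ignores comparator size", {
  base <- c(30, 70, 200, 700)
  widths <- sapply(c(1, 2, 4, 8), function(k) {
    est <- ror_ci(base[1] * k, base[2] * k, base[3] * k, base[4] * k)
    log(est$ci_high) - log(est$ci_low)
  })
  expect_true(all(diff(widths) < 0))
  # scaling only the comparator row leaves the ROR unchanged
  a <- ror_ci(30, 70, 200, 700)
  b <- ror_ci(30, 70, 200 * 5, 700 * 5)
  expect_equal(a$ror, b$ror)
  expect_lt(log(b$ci_high) - log(b$ci_low), log(a$ci_high) - log(a$ci_low))
})

test_that("the signal rule is a strict threshold on the lower bound", {
  expect_false(detect_signal(1.5, 1.0))
  expect_true(detect_signal(1.5, 1.0000001))
  expect_false(detect_signal(NA_real_, NA_real_))
})

test_that("Fisher p-values are exact and symmetric where they must be", {
  expect_equal(fisher_exact_p(1, 1, 1, 1), 1)
  p <- fisher_exact_p(10, 0, 0, 10)
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(p, 0.001)
})

test_that("Fisher p-values match the reference implementation", {
  set.seed(7)
  for (i in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(10:60, 1), prob = runif(4)))
    mine <- fisher_exact_p(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("the screen produces one row per drug and stratum", {
  ts <- glucose_terms()
  r <- simulate_reports(synthetic_config(n_cases = 3000, seed = 23,
    drug_specs = data.frame(
      drug_name = paste0("drug_", letters[1:5]),
      exposure_prob = rep(0.03, 5),
      true_ror = rep(1, 5)
    ))) |>
    deduplicate_reports() |>
    apply_eligibility()
  res <- ror_screen(r, paste0("drug_", letters[1:5]), ts)
  expect_equal(nrow(res), 25)
  expect_equal(dplyr::n_distinct(res$drug), 5)
  expect_equal(dplyr::n_distinct(res$stratum), 5)
  expect_true(all(res$n11 + res$n12 + res$n21 + res$n22 <= nrow(r)))

  expect_equal(nrow(ror_screen(r, character(0), ts)), 0)

  td <- tidy(res)
  expect_equal(names(td), c("drug", "stratum", "estimate", "conf.low",
                            "conf.high", "p.value", "signal"))
  g <- glance(res)
  expect_equal(g$n_drugs, 5)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("only the drug with an injected effect is flagged", {
  ts <- glucose_terms()
  r <- simulate_reports(synthetic_config(n_cases = 100000, seed = 29,
    drug_specs = data.frame(
      drug_name = c("drug_a", "drug_b", "drug_c"),
      exposure_prob = c(0.05, 0.05, 0.05),
      true_ror = c(4, 1, 1)
    ))) |>
    deduplicate_reports() |>
    apply_eligibility()
  res <- ror_screen(r, c("drug_a", "drug_b", "drug_c"), ts,
                    strata = list(stratum_spec()))
  expect_true(res$signal[res$drug == "drug_a"])
  expect_false(any(res$signal[res$drug != "drug_a"]))
})
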