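test_that("contingency tables follow declared level order and catch bad input", {
  recs <- data.frame(
    severity = c("Moderate", "Mild", "Moderate", "Not recorded"),
    quality_group = c("High", "Low", "High", "Low"))
  tab <- contingency_table(recs, "severity", "quality_group")
  expect_identical(rownames(tab), aqua_factor_levels()$severity)
  expect_identical(colnames(tab), c("High", "Low"))
  expect_identical(sum(tab), 4L)
  expect_identical(as.integer(tab["Moderate", "High"]), 2L)

  one <- contingency_table(recs[2, ], "severity", "quality_group")
  expect_identical(as.integer(one["Mild", "Low"]), 1L)
  expect_identical(sum(one), 1L)

  expect_error(contingency_table(recs[0, ], "severity", "quality_group"),
               "no records")
  recs$severity[1] <- "Catastrophic"
  expect_error(contingency_table(recs, "severity", "quality_group"),
               "Catastrophic")
})

test_that("Pearson chi-square reproduces the published group comparisons", {
  tabs <- printed_tables()
  expect_warning(r_sev <- chi_square_test(tabs$severity_quality), "below 5")
  expect_identical(r_sev$method, "pearson_chi_square")
  expect_identical(r_sev$df, 5L)
  expect_equal(round(r_sev$p_value, 3), 0.008)

  expect_warning(r_rx <- chi_square_test(tabs$reaction_quality))
  expect_equal(round(r_rx$p_value, 2), 0.13)

  # identical row proportions: statistic exactly 0, p = 1
  flat <- rbind(c(10, 20), c(5, 10))
  r0 <- suppressWarnings(chi_square_test(flat))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  expect_error(chi_square_test(rbind(c(0, 0), c(3, 4))), "margins")
  expect_error(chi_square_test(matrix(1:3, 1)), "2x2")
})

test_that("Fisher exact matches enumeration and the published 2x2 p-value", {
  tabs <- printed_tables()
  r <- fisher_exact_2x2(tabs$reporter_phase)
  expect_identical(r$method, "fisher_exact_2x2")
  expect_equal(round(r$p_value, 2), 0.71)
  expect_true(is.na(r$statistic))

  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(1:6, 2, 3)), "chi_square_test")

  # random 2x2 tables with margins <= 12 against exhaustive enumeration
  set.seed(70)
  for (rep in 1:50) {
    t <- matrix(sample(0:6, 4, replace = TRUE), 2, 2)
    if (sum(t) == 0) next
    expect_equal(fisher_exact_2x2(t)$p_value, fisher_enum_p(t),
                 tolerance = 1e-12)
  }
})

test_that("both tests are invariant to simultaneous row/column permutation", {
  t <- printed_tables()$unit_phase
  perm <- t[c(3, 1, 4, 2), c(2, 1)]
  expect_equal(suppressWarnings(chi_square_test(perm))$p_value,
               suppressWarnings(chi_square_test(t))$p_value, tolerance = 1e-12)
  f <- printed_tables()$reporter_phase
  expect_equal(fisher_exact_2x2(f[2:1, 2:1])$p_value,
               fisher_exact_2x2(f)$p_value, tolerance = 1e-12)
})

test_that("enumeration point probabilities sum to one over the support", {
  set.seed(80)
  for (rep in 1:20) {
    n <- sample(5:40, 1); r1 <- sample(0:n, 1); c1 <- sample(0:n, 1)
    amin <- max(0L, r1 + c1 - n); amax <- min(r1, c1)
    expect_equal(sum(dhyper(amin:amax, c1, n - c1, r1)), 1, tolerance = 1e-10)
  }
})

test_that("asymptotic p agrees with permutation Monte Carlo on well-filled tables", {
  # in the asymptotic regime (all expected counts large) the Pearson upper-tail
  # p and the exact conditional permutation p coincide to Monte-Carlo accuracy
  big <- rbind(c(120, 95, 110), c(100, 118, 92))
  pp <- perm_chisq_p(big, n_draws = 40000, seed = 2)
  pc <- chi_square_test(big)$p_value
  expect_lt(abs(pc - pp$p), 3 * pp$se)
})

test_that("compare_groups dispatches by table shape as the footnotes do", {
  fx <- cohort_fixture()
  meta <- fx$metadata
  r1 <- compare_groups(meta, "reporter_vocation", "phase")
  expect_identical(r1$method, "fisher_exact_2x2")
  r2 <- suppressWarnings(compare_groups(meta, "reporting_unit", "phase"))
  expect_identical(r2$method, "pearson_chi_square")
  expect_equal(round(r2$p_value, 2), 0.19)
  r3 <- suppressWarnings(compare_groups(meta, "reaction_type", "phase"))
  expect_equal(round(r3$p_value, 2), 0.09)
})
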