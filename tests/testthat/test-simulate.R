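test_that("simulation configs validate their probability inputs", {
  expect_error(simulation_config(rater_noise = 1.5), "rater_noise")
  bad_profile <- default_quality_profile()
  bad_profile$timeline <- c("0" = 0.6, "1" = 0.6)
  expect_error(simulation_config(element_quality_profile = bad_profile,
                                 rater_noise = 0.1), "sum to 1")
})

test_that("latent reports are reproducible and respect the profile", {
  cfg <- simulation_config(n_reports = 30, rater_noise = 0.1, seed = 123)
  a <- generate_true_reports(cfg)
  b <- generate_true_reports(cfg)
  expect_identical(a, b)                       # same seed, byte-identical
  c_ <- generate_true_reports(simulation_config(n_reports = 30,
                                                rater_noise = 0.1, seed = 124))
  expect_false(identical(a$truth, c_$truth))   # different seeds decorrelate

  # profile concentrated on the maxima: every latent total is 12
  prof <- default_quality_profile()
  prof <- lapply(prof, function(p) { p[] <- 0; p[length(p)] <- 1; p })
  cfg_max <- simulation_config(n_reports = 20,
                               element_quality_profile = prof,
                               rater_noise = 0.1, seed = 1)
  tr <- generate_true_reports(cfg_max)$truth
  expect_true(all(total_score(tr) == 12L))
})

test_that("generated metadata frequencies sit inside exact binomial bands", {
  cfg <- simulation_config(n_reports = 4000, rater_noise = 0.1, seed = 321)
  meta <- generate_true_reports(cfg)$metadata
  p_sev <- default_metadata_frequencies()$severity
  counts <- table(factor(meta$severity, names(p_sev)))
  for (lev in names(p_sev)) {
    lo <- qbinom(0.005, 4000, p_sev[[lev]])
    hi <- qbinom(0.995, 4000, p_sev[[lev]])
    expect_gte(counts[[lev]], lo)
    expect_lte(counts[[lev]], hi)
  }
})

test_that("rater noise perturbs scores as specified at the extremes", {
  cfg0 <- simulation_config(n_reports = 25, k_assessors = 3,
                            rater_noise = 0, seed = 9)
  sim0 <- simulate_cohort(cfg0)
  for (id in aqua_elements()) {
    m <- matrix(sim0$assessments[[id]], nrow = 25)
    expect_true(all(m == sim0$truth[[id]]))    # zero noise copies the truth
  }
  expect_s3_class(sim0$assessments, "aqua_assessments")  # always valid

  # full noise on a binary element: half the copies move (the other half of
  # proposed shifts are clamped at the scale boundary and lost)
  cfg1 <- simulation_config(n_reports = 4000, k_assessors = 1,
                            rater_noise = 1, seed = 10)
  sim1 <- simulate_cohort(cfg1)
  flip_rate <- mean(sim1$assessments$timeline != sim1$truth$timeline)
  expect_gt(flip_rate, 0.45)
  expect_lt(flip_rate, 0.55)
})

test_that("closed-form population alpha matches a large-sample estimate", {
  eps <- 0.2
  pop <- population_alpha(eps, k = 2)
  cfg <- simulation_config(n_reports = 60000, k_assessors = 2,
                           rater_noise = eps, seed = 77)
  est <- cronbach_alpha(score_matrix(simulate_cohort(cfg)$assessments))
  expect_equal(est, pop, tolerance = 0.02)
  expect_equal(population_alpha(0, k = 2), 1)
})

test_that("noise calibration inverts the population-alpha curve", {
  for (target in c(0.8, 0.9, 0.95)) {
    eps <- calibrate_noise(target, k = 2)
    expect_equal(population_alpha(eps, k = 2), target, tolerance = 1e-8)
  }
  # the default config calibrates itself to 0.9
  cfg <- simulation_config(n_reports = 10, seed = 1)
  expect_equal(population_alpha(cfg$rater_noise, k = 2), 0.9, tolerance = 1e-8)
})

test_that("estimated alpha decreases monotonically with rater noise", {
  grid <- c(0.05, 0.15, 0.35, 0.7)
  set.seed(2024)
  means <- vapply(grid, function(eps) {
    mean(replicate(200, {
      cfg <- simulation_config(n_reports = 30, k_assessors = 2,
                               rater_noise = eps)
      cronbach_alpha(score_matrix(generate_rater_scores(
        generate_true_reports(cfg), cfg)))
    }))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
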