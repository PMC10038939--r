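test_that("default rubric matches the published instrument", {
  r <- default_rubric()
  expect_s3_class(r, "aqua_rubric")
  expect_identical(r$elements$element_id, aqua_elements())
  expect_identical(r$elements$max_score, c(2L, 2L, 2L, 2L, 1L, 1L, 2L))
  expect_identical(r$total_max, 12L)
})

test_that("rubric JSON round-trips and rejects inconsistent allowed scores", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(elements = data.frame(
    element_id = c("a", "b"), name = c("A", "B"), max_score = c(2L, 1L))),
    path)
  r <- read_rubric(path)
  expect_identical(r$total_max, 3L)

  bad <- tempfile(fileext = ".json")
  writeLines('{"elements":[{"element_id":"a","name":"A",
               "allowed_scores":[0,2],"max_score":2}]}', bad)
  expect_error(read_rubric(bad), "allowed_scores")
  expect_error(aqua_rubric(data.frame(element_id = "x", name = "X",
                                      max_score = 3)), "max_score")
})

test_that("assessment validation accepts legal scores and names offenders", {
  a <- perfect_assessment()
  expect_identical(sum(validate_assessment(a)), 12L)

  a_bad <- a; a_bad$timeline <- 2
  expect_error(validate_assessment(a_bad), "score 2 not allowed for timeline")

  a_missing <- a[names(a) != "management"]
  expect_error(validate_assessment(a_missing), "management")

  a_neg <- a; a_neg$key_events <- -1
  expect_error(validate_assessment(a_neg), "key_events")
  a_frac <- a; a_frac$key_events <- 1.5
  expect_error(validate_assessment(a_frac), "key_events")
})

test_that("total score sums elements and is monotone in each", {
  expect_identical(total_score(perfect_assessment()), 12L)
  zeros <- lapply(perfect_assessment(), function(x) 0)
  expect_identical(total_score(zeros), 0L)
  a11 <- list(prev_adr_history = 2, actual_reaction = 2, key_events = 2,
              suspected_medications = 1, timeline = 1, management = 1,
              outcome_sequelae = 2)
  expect_identical(total_score(a11), 11L)

  maxes <- c(2, 2, 2, 2, 1, 1, 2)
  set.seed(101)
  for (rep in 1:20) {
    a <- as.list(vapply(maxes, function(m) sample(0:m, 1), numeric(1)))
    names(a) <- aqua_elements()
    el <- sample(which(unlist(a) < maxes - 0L + 1e-9), 1)
    if (a[[el]] < maxes[el]) {
      bumped <- a; bumped[[el]] <- a[[el]] + 1
      expect_gt(total_score(bumped), total_score(a))
    }
  }
})

test_that("quality categories partition 0..12 and align with the threshold", {
  expect_equal(as.character(categorize(c(12, 11, 10, 9, 8, 7, 0))),
               c("Excellent", "Good", "Good", "Moderate", "Moderate",
                 "Poor", "Poor"))
  expect_error(categorize(13), "0, 12")
  expect_error(categorize(-1), "0, 12")
  expect_error(is_high_quality(13), "0, 12")

  s <- 0:12
  expect_false(anyNA(categorize(s)))               # every score has a label
  expect_identical(is_high_quality(s),
                   categorize(s) %in% c("Excellent", "Good"))
  expect_true(is_high_quality(10))
  expect_false(is_high_quality(9))
})

test_that("incomplete elements are exactly those below their maximum", {
  expect_length(incomplete_elements(perfect_assessment()), 0)
  a <- perfect_assessment(); a$suspected_medications <- 1
  expect_identical(incomplete_elements(a), "suspected_medications")
  zeros <- lapply(perfect_assessment(), function(x) 0)
  expect_setequal(incomplete_elements(zeros), aqua_elements())

  # |incomplete| = 0 iff total = 12
  maxes <- c(2, 2, 2, 2, 1, 1, 2)
  set.seed(11)
  for (rep in 1:25) {
    a <- as.list(vapply(maxes, function(m) sample(0:m, 1), numeric(1)))
    names(a) <- aqua_elements()
    expect_identical(length(incomplete_elements(a)) == 0L,
                     total_score(a) == 12L)
  }
})

test_that("assessment tables validate row-wise with duplicates rejected", {
  df <- random_assessments(4, 2, seed = 5)
  expect_s3_class(df, "aqua_assessments")
  expect_error(as_assessments(rbind(as.data.frame(df), as.data.frame(df)[1, ])),
               "duplicate")
  bad <- as.data.frame(df); bad$timeline[2] <- 2
  expect_error(as_assessments(bad), "row 2")
})
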