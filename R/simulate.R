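# Synthetic multi-rater cohorts: latent per-report element scores, i.i.d.
# rater perturbation noise, and categorical report metadata, so that the
# scoring, reliability and summary machinery can be validated without any
# real ADR data.

#' Default per-element score profile
#'
#' Probability vector over the allowed scores of each element. The mass below
#' the maximum matches the observed element-incompleteness rates of the
#' 70-report reference cohort (17.1%, 27.1%, 35.7%, 37.1%, 8.6%, 8.6%, 8.6%);
#' for two-point elements that mass is split 2:1 between the partial score 1
#' and score 0 (partial completion is the commoner failure mode).
#'
#' @return named list; each entry a probability vector named "0","1"(, "2").
#' @export
default_quality_profile <- function() {
  rates <- c(prev_adr_history = 12, actual_reaction = 19, key_events = 25,
             suspected_medications = 26, timeline = 6, management = 6,
             outcome_sequelae = 6) / 70
  maxes <- c(2, 2, 2, 2, 1, 1, 2)
  out <- vector("list", 7)
  names(out) <- names(rates)
  for (i in seq_along(rates)) {
    r <- rates[[i]]
    if (maxes[i] == 2) {
      p <- c(r / 3, 2 * r / 3, 1 - r)
    } else {
      p <- c(r, 1 - r)
    }
    names(p) <- as.character(0:maxes[i])
    out[[i]] <- p
  }
  out
}

#' Default metadata category frequencies
#'
#' Relative frequencies of the standard report descriptors in the 70-report
#' reference cohort, including the 20/50 development/evaluation phase split
#' and the per-mention medication-class distribution (112 mentions over 70
#' reports, i.e. 1.6 classes per report on average).
#'
#' @return named list of probability vectors plus `classes_per_report`, the
#'   distribution of the number of medication-class mentions per report.
#' @export
default_metadata_frequencies <- function() {
  lv <- aqua_factor_levels()
  f <- function(counts, levels) stats::setNames(counts / sum(counts), levels)
  list(
    reporter_vocation = f(c(60, 10), lv$reporter_vocation),
    reporting_unit = f(c(37, 14, 10, 9), lv$reporting_unit),
    reaction_type = f(c(13, 18, 14, 10, 7, 8), lv$reaction_type),
    severity = f(c(7, 33, 16, 7, 2, 5), lv$severity),
    phase = f(c(20, 50), lv$phase),
    medication_classes = f(c(3, 1, 3, 2, 5, 70, 2, 3, 4, 4, 15),
                           lv$medication_classes),
    classes_per_report = c("1" = 0.4, "2" = 0.6)
  )
}

.check_probs <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("probabilities for ", what, " must be non-negative and sum to 1")
  }
  p
}

#' Configuration for a simulated multi-rater cohort
#'
#' @param n_reports number of reports; default 70, the reference cohort size.
#' @param k_assessors raters per report; default 2, the prospective-phase
#'   design.
#' @param element_quality_profile per-element score distributions
#'   ([default_quality_profile()]).
#' @param rater_noise probability that an assessor perturbs a true element
#'   score by one point; `NULL` (default) calibrates it with
#'   [calibrate_noise()] so the population reliability of total scores equals
#'   0.9, the agreement level of the instrument's evaluation rounds.
#' @param metadata_frequencies category probabilities
#'   ([default_metadata_frequencies()]).
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @return list of class `aqua_sim_config`.
#' @export
simulation_config <- function(n_reports = 70, k_assessors = 2,
                              element_quality_profile = default_quality_profile(),
                              rater_noise = NULL,
                              metadata_frequencies = default_metadata_frequencies(),
                              seed = NULL) {
  stopifnot(n_reports >= 1, k_assessors >= 1)
  for (id in names(element_quality_profile)) {
    .check_probs(element_quality_profile[[id]], id)
  }
  for (id in setdiff(names(metadata_frequencies), "classes_per_report")) {
    .check_probs(metadata_frequencies[[id]], id)
  }
  if (is.null(rater_noise)) {
    rater_noise <- calibrate_noise(0.9, element_quality_profile, k_assessors)
  }
  if (rater_noise < 0 || rater_noise > 1) stop("rater_noise must be in [0, 1]")
  if (!is.null(seed)) stopifnot(seed == as.integer(seed), abs(seed) < 2^30)
  structure(
    list(n_reports = as.integer(n_reports), k_assessors = as.integer(k_assessors),
         element_quality_profile = element_quality_profile,
         rater_noise = rater_noise,
         metadata_frequencies = metadata_frequencies, seed = seed),
    class = "aqua_sim_config"
  )
}

# conditional mean and variance of the +/-1 clamped perturbation, given the
# true score s on a 0..M scale; internal
.noise_moments <- function(s, M, eps) {
  if (s > 0 && s < M) {
    c(mean = 0, var = eps)
  } else {
    mu <- if (s == 0) eps / 2 else -eps / 2
    c(mean = mu, var = eps / 2 - eps^2 / 4)
  }
}

#' Population reliability of simulated total scores
#'
#' Closed-form large-sample value of Cronbach's alpha (consistency,
#' average measures) for total scores under the simulation model: latent
#' element scores drawn independently from the profile, each of k assessors
#' independently perturbing each element by one point (clamped to the allowed
#' range) with probability `epsilon`. With B the between-report variance of
#' the expected observed total and W the mean within-report noise variance,
#' alpha = B / (B + W/k).
#'
#' @param epsilon perturbation probability.
#' @param profile per-element score distributions.
#' @param k number of assessors.
#' @return the population alpha.
#' @export
population_alpha <- function(epsilon, profile = default_quality_profile(),
                             k = 2) {
  B <- 0; W <- 0
  for (id in names(profile)) {
    p <- profile[[id]]
    scores <- as.numeric(names(p))
    M <- max(scores)
    mom <- t(vapply(scores, .noise_moments, numeric(2), M = M, eps = epsilon))
    u <- scores + mom[, "mean"]           # conditional mean observed score
    B <- B + sum(p * u^2) - sum(p * u)^2  # Var of conditional mean
    W <- W + sum(p * mom[, "var"])        # mean conditional noise variance
  }
  if (W == 0) return(1)
  B / (B + W / k)
}

#' Calibrate rater noise to a target population reliability
#'
#' Solves `population_alpha(eps) = target` for the perturbation probability
#' by root finding; alpha is strictly decreasing in the noise level over the
#' relevant range.
#'
#' @param target target population alpha (e.g. 0.9).
#' @param profile,k as in [population_alpha()].
#' @return the calibrated epsilon.
#' @export
calibrate_noise <- function(target = 0.9, profile = default_quality_profile(),
                            k = 2) {
  stopifnot(target > 0, target < 1)
  lo_alpha <- population_alpha(1, profile, k)
  if (lo_alpha > target) {
    stop("target alpha ", target, " unreachable: even full noise gives alpha ",
         signif(lo_alpha, 3))
  }
  stats::uniroot(function(e) population_alpha(e, profile, k) - target,
                 interval = c(1e-9, 1), tol = 1e-10)$root
}

#' Generate latent reports: true element scores plus metadata
#'
#' Element scores are drawn independently per element from the configured
#' profile; metadata categories from the configured frequencies. Fully
#' reproducible from the config seed.
#'
#' @param cfg an `aqua_sim_config`.
#' @return list with `truth` (data.frame: report_id + one column per element)
#'   and `metadata` (data.frame of report descriptors, medication classes as
#'   a semicolon-separated per-mention list).
#' @export
generate_true_reports <- function(cfg) {
  stopifnot(inherits(cfg, "aqua_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_reports
  ids <- sprintf("S%03d", seq_len(n))
  truth <- data.frame(report_id = ids, stringsAsFactors = FALSE)
  for (id in names(cfg$element_quality_profile)) {
    p <- cfg$element_quality_profile[[id]]
    truth[[id]] <- sample(as.integer(names(p)), n, replace = TRUE, prob = p)
  }
  mf <- cfg$metadata_frequencies
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  n_cls <- sample(as.integer(names(mf$classes_per_report)), n, replace = TRUE,
                  prob = mf$classes_per_report)
  classes <- vapply(n_cls, function(m) {
    paste(sample(names(mf$medication_classes), m, replace = TRUE,
                 prob = mf$medication_classes), collapse = ";")
  }, character(1))
  metadata <- data.frame(
    report_id = ids,
    reporter_vocation = draw(mf$reporter_vocation),
    reporting_unit = draw(mf$reporting_unit),
    reaction_type = draw(mf$reaction_type),
    severity = draw(mf$severity),
    phase = draw(mf$phase),
    medication_classes = classes,
    stringsAsFactors = FALSE
  )
  list(truth = truth, metadata = metadata)
}

#' Generate per-assessor scores from latent reports
#'
#' Each assessor independently copies every true element score and, with
#' probability `rater_noise`, shifts it by one point up or down (equal odds),
#' clamping to the element's allowed range — so a shift at the boundary of
#' the scale is lost, mimicking a rater who cannot over- or under-score past
#' the rubric limits.
#'
#' @param truth the `truth` data.frame from [generate_true_reports()] (or a
#'   list containing one).
#' @param cfg an `aqua_sim_config`.
#' @return an [as_assessments()]-validated long table with assessor ids
#'   `"A1"..Ak`.
#' @export
generate_rater_scores <- function(truth, cfg) {
  stopifnot(inherits(cfg, "aqua_sim_config"))
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$truth)) {
    truth <- truth$truth
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  ids <- names(cfg$element_quality_profile)
  maxes <- vapply(cfg$element_quality_profile,
                  function(p) max(as.integer(names(p))), integer(1))
  n <- nrow(truth); k <- cfg$k_assessors
  out <- vector("list", k)
  for (j in seq_len(k)) {
    block <- truth[, ids, drop = FALSE]
    for (e in seq_along(ids)) {
      s <- block[[e]]
      hit <- stats::runif(n) < cfg$rater_noise
      dir <- sample(c(-1L, 1L), n, replace = TRUE)
      s2 <- s + ifelse(hit, dir, 0L)
      block[[e]] <- pmin(pmax(s2, 0L), maxes[e])
    }
    out[[j]] <- cbind(
      data.frame(report_id = truth$report_id, assessor_id = sprintf("A%d", j),
                 stringsAsFactors = FALSE),
      block)
  }
  as_assessments(do.call(rbind, out))
}

#' Simulate a complete multi-rater cohort
#'
#' Convenience wrapper: latent reports, then rater scores.
#'
#' @param cfg an `aqua_sim_config`.
#' @return list with `truth`, `metadata`, `assessments`.
#' @export
simulate_cohort <- function(cfg) {
  tr <- generate_true_reports(cfg)
  list(truth = tr$truth, metadata = tr$metadata,
       assessments = generate_rater_scores(tr$truth, cfg))
}
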