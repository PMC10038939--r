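# Independent oracles and shared fixtures for the test suite.

# a complete assessment at the element maxima, as a named list
perfect_assessment <- function() {
  list(prev_adr_history = 2, actual_reaction = 2, key_events = 2,
       suspected_medications = 2, timeline = 1, management = 1,
       outcome_sequelae = 2)
}

# random valid assessment table: n reports x k assessors, uniform scores
random_assessments <- function(n, k, seed) {
  set.seed(seed)
  maxes <- c(2, 2, 2, 2, 1, 1, 2)
  rows <- expand.grid(report_id = sprintf("r%02d", seq_len(n)),
                      assessor_id = sprintf("a%d", seq_len(k)),
                      stringsAsFactors = FALSE)
  for (i in seq_along(aqua_elements())) {
    rows[[aqua_elements()[i]]] <- sample(0:maxes[i], nrow(rows), replace = TRUE)
  }
  as_assessments(rows)
}

# Cronbach's alpha via an independent route: two-way ANOVA mean squares from
# lm(), alpha = 1 - MS_residual / MS_between-reports
anova_alpha <- function(m) {
  d <- data.frame(y = as.vector(m),
                  report = factor(rep(seq_len(nrow(m)), ncol(m))),
                  assessor = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- anova(lm(y ~ report + assessor, data = d))
  1 - tab["Residuals", "Mean Sq"] / tab["report", "Mean Sq"]
}

# exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric point
# probabilities not exceeding the observed one (point-probability convention)
fisher_enum_p <- function(t, tie_tol = 1e-7) {
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  amin <- max(0L, r1 + c1 - n); amax <- min(r1, c1)
  p_all <- dhyper(amin:amax, c1, n - c1, r1)
  sum(p_all[p_all <= p_all[t[1, 1] - amin + 1] * (1 + tie_tol)])
}

# permutation p for the Pearson statistic under fixed margins
perm_chisq_p <- function(t, n_draws = 100000, seed = 1) {
  set.seed(seed)
  stat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  obs <- stat(t)
  sims <- vapply(stats::r2dtable(n_draws, rowSums(t), colSums(t)), stat,
                 numeric(1))
  p <- mean(sims >= obs - 1e-9)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# the published contingency tables (characteristic levels x groups)
printed_tables <- function() {
  list(
    severity_quality = cbind(High = c(3, 29, 13, 5, 1, 1),
                             Low = c(4, 4, 3, 2, 1, 4)),
    reaction_quality = cbind(High = c(7, 14, 14, 7, 5, 5),
                             Low = c(6, 4, 0, 3, 2, 3)),
    reporter_quality = cbind(High = c(45, 7), Low = c(15, 3)),
    reporter_phase = cbind(development = c(18, 2), evaluation = c(42, 8)),
    unit_phase = cbind(development = c(12, 5, 0, 3),
                       evaluation = c(25, 9, 10, 6)),
    reaction_phase = cbind(development = c(4, 2, 2, 5, 4, 3),
                           evaluation = c(9, 16, 12, 5, 3, 5)),
    severity_phase = cbind(development = c(1, 12, 2, 3, 0, 2),
                           evaluation = c(6, 21, 14, 4, 2, 3))
  )
}

# two-way Gaussian rater model with known population alpha (consistency,
# average measures): sigma_e^2 chosen so alpha = sb2 / (sb2 + se2/k)
gaussian_score_matrix <- function(n, k, alpha) {
  se2 <- k * (1 / alpha - 1)
  rnorm(n) + matrix(rnorm(n * k, sd = sqrt(se2)), n, k)
}
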