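# Inter-rater reliability of total scores: Cronbach's alpha, equivalently the
# two-way consistency average-measures ICC, with Feldt F confidence intervals.

#' Build a report x assessor matrix of total scores
#'
#' Pivots a long assessment table into the n x k matrix that the reliability
#' functions consume. Reports without a score from every assessor are dropped
#' listwise (with a message giving the count); imputation is deliberately not
#' offered.
#'
#' @param assessments data.frame as accepted by [as_assessments()].
#' @param rubric an `aqua_rubric`.
#' @return numeric matrix with report ids as row names and assessor ids as
#'   column names.
#' @export
score_matrix <- function(assessments, rubric = default_rubric()) {
  df <- as.data.frame(assessments)
  totals <- total_score(df, rubric)
  reports <- unique(df$report_id)
  assessors <- unique(df$assessor_id)
  m <- matrix(NA_real_, nrow = length(reports), ncol = length(assessors),
              dimnames = list(reports, assessors))
  m[cbind(match(df$report_id, reports), match(df$assessor_id, assessors))] <- totals
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    message(sum(!complete), " report(s) dropped listwise (not scored by every assessor)")
    m <- m[complete, , drop = FALSE]
  }
  m
}

.check_score_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("score matrix must be numeric")
  if (anyNA(m)) stop("score matrix must be complete (no missing cells)")
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("reliability needs at least 2 reports and 2 assessors")
  }
  m
}

#' Cronbach's alpha for a score matrix
#'
#' With k assessors as "items", alpha = k/(k-1) * (1 - sum of per-assessor
#' variances / variance of per-report row sums), using sample variances
#' (denominator n-1). This equals the two-way, consistency, average-measures
#' intraclass correlation, and via the ANOVA identity also equals
#' 1 - MS_residual / MS_between-reports.
#'
#' @param m numeric n x k matrix (reports x assessors), complete.
#' @return alpha, a real number \eqn{\le} 1 (negative values are possible and
#'   indicate disagreement beyond chance).
#' @export
cronbach_alpha <- function(m) {
  m <- .check_score_matrix(m)
  k <- ncol(m)
  var_total <- stats::var(rowSums(m))
  if (var_total == 0) {
    stop("reliability is undefined: all reports have identical score sums (no between-report variance)")
  }
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / var_total)
}

# two-way ANOVA mean squares for a complete reports x assessors matrix
.ms_decomposition <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_res <- ss_tot - ss_rows - ss_cols
  list(ms_between = ss_rows / (n - 1),
       ms_residual = ss_res / ((n - 1) * (k - 1)),
       df1 = n - 1, df2 = (n - 1) * (k - 1))
}

#' Inter-rater reliability with confidence interval
#'
#' Point estimate by [cronbach_alpha()]; two-sided confidence interval by
#' Feldt's F method: with F = MS_between / MS_residual on (n-1) and
#' (n-1)(k-1) degrees of freedom, the bounds are
#' `1 - (1-alpha) * qf(1 - (1-level)/2, df1, df2)` (lower) and
#' `1 - (1-alpha) * qf((1-level)/2, df1, df2)` (upper). A nonparametric
#' bootstrap over reports is available as a sensitivity check.
#'
#' @param m numeric n x k score matrix, or an assessment table coercible via
#'   [score_matrix()].
#' @param level confidence level in (0, 1); default 0.95.
#' @param ci `"feldt"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates when `ci = "bootstrap"`.
#' @return object of class `aqua_reliability`: list with `alpha`, `ci_low`,
#'   `ci_high`, `level`, `n_reports`, `k_assessors`, `ci_method`. When the
#'   residual mean square is zero (assessors agree perfectly up to per-rater
#'   constants) the interval is undefined and returned as `NA` with a warning.
#' @export
reliability <- function(m, level = 0.95, ci = c("feldt", "bootstrap"),
                        n_boot = 2000) {
  ci <- match.arg(ci)
  if (is.data.frame(m)) m <- score_matrix(m)
  m <- .check_score_matrix(m)
  if (level <= 0 || level >= 1) stop("confidence level must be in (0, 1)")
  alpha <- cronbach_alpha(m)
  ms <- .ms_decomposition(m)
  if (ci == "feldt") {
    if (ms$ms_residual <= .Machine$double.eps * abs(ms$ms_between)) {
      warning("assessors agree perfectly (zero residual mean square); confidence interval undefined")
      lo <- hi <- NA_real_
    } else {
      a2 <- (1 - level) / 2
      lo <- 1 - (1 - alpha) * stats::qf(1 - a2, ms$df1, ms$df2)
      hi <- 1 - (1 - alpha) * stats::qf(a2, ms$df1, ms$df2)
    }
  } else {
    boots <- replicate(n_boot, {
      idx <- sample.int(nrow(m), replace = TRUE)
      mb <- m[idx, , drop = FALSE]
      if (stats::var(rowSums(mb)) == 0) NA_real_ else cronbach_alpha(mb)
    })
    qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  structure(
    list(alpha = alpha, ci_low = lo, ci_high = hi, level = level,
         n_reports = nrow(m), k_assessors = ncol(m), ci_method = ci),
    class = "aqua_reliability"
  )
}

#' @export
print.aqua_reliability <- function(x, digits = 3, ...) {
  cat(sprintf("Inter-rater reliability (Cronbach's alpha / ICC consistency, average measures)\n"))
  cat(sprintf("  reports: %d   assessors: %d\n", x$n_reports, x$k_assessors))
  cat(sprintf("  alpha = %.*f", digits, x$alpha))
  if (is.finite(x$ci_low)) {
    cat(sprintf("   %g%% CI [%.*f, %.*f] (%s)\n",
                100 * x$level, digits, x$ci_low, digits, x$ci_high, x$ci_method))
  } else {
    cat(sprintf("   %g%% CI undefined\n", 100 * x$level))
  }
  invisible(x)
}

#' @export
confint.aqua_reliability <- function(object, parm = "alpha", level = NULL, ...) {
  out <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
                dimnames = list("alpha", c("lower", "upper")))
  out
}

#' Flag reports whose assessors disagree by more than a threshold
#'
#' During rubric development, reports whose assessor total scores spread by
#' more than two points are flagged for discussion. A report is flagged when
#' max(total) - min(total) strictly exceeds `threshold`; a spread of exactly
#' `threshold` is not flagged. Reports with a single assessor are skipped
#' with a message.
#'
#' @param assessments long-format assessment table.
#' @param threshold integer; default 2.
#' @param rubric an `aqua_rubric`.
#' @return character vector of flagged report ids.
#' @export
flag_discrepancies <- function(assessments, threshold = 2,
                               rubric = default_rubric()) {
  df <- as.data.frame(assessments)
  totals <- total_score(df, rubric)
  spread <- tapply(totals, df$report_id, function(t) max(t) - min(t))
  n_each <- tapply(totals, df$report_id, length)
  single <- names(n_each)[n_each < 2]
  if (length(single)) {
    message(length(single), " report(s) with a single assessor skipped: ",
            paste(single, collapse = ", "))
  }
  eligible <- names(n_each)[n_each >= 2]
  flagged <- eligible[spread[eligible] > threshold]
  # preserve input report order
  flagged[order(match(flagged, unique(df$report_id)))]
}
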