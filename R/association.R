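# Contingency tables and the two univariable tests used for group
# comparisons: Pearson chi-square (no continuity correction) and the
# two-sided Fisher exact test for 2x2 tables.

#' Declared category orders for the standard report metadata factors
#'
#' Row order of summary tables follows these declared orders; "Not recorded"
#' severity is a legal, distinct level.
#'
#' @return named list of character vectors.
#' @export
aqua_factor_levels <- function() {
  list(
    reporter_vocation = c("Pharmacist", "Doctor"),
    reporting_unit = c("Medical", "Surgical", "ED", "Other"),
    reaction_type = c("Immediate hypersensitivity",
                      "Delayed hypersensitivity, non-SCAR",
                      "Delayed hypersensitivity, single-organ involvement",
                      "Delayed hypersensitivity, SCAR",
                      "Non-immunological",
                      "Other"),
    severity = c("Mild", "Moderate", "Severe", "Life-threatening", "Fatal",
                 "Not recorded"),
    phase = c("development", "evaluation"),
    quality_group = c("High", "Low"),
    medication_classes = c("Anaesthetic agents", "Antiemetics",
                           "Antiepileptics", "Antihypertensives",
                           "Antimetabolites", "Antimicrobials",
                           "Iron formulations", "NSAIDs", "Opioids",
                           "Radiocontrast agents", "Others")
  )
}

.as_declared_factor <- function(x, name, levels = NULL) {
  if (is.factor(x)) return(x)
  if (is.null(levels)) levels <- aqua_factor_levels()[[name]]
  if (is.null(levels)) levels <- unique(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad)) {
    stop("unknown level(s) for '", name, "': ", paste(bad, collapse = ", "))
  }
  factor(x, levels = levels)
}

#' Cross-tabulate two categorical record fields
#'
#' Builds an r x c count table whose row/column order follows the declared
#' category order (the packaged orders in [aqua_factor_levels()] for the
#' standard fields, or the factor levels of the input columns). Values outside
#' the declared levels are an error.
#'
#' @param records data.frame, one row per record.
#' @param row_factor,col_factor column names.
#' @param row_levels,col_levels optional explicit level orders.
#' @param drop_empty drop levels with zero count in both margins? Default
#'   FALSE (printed tables keep declared levels that occur in the data).
#' @return a `table` (counts) with named dimnames.
#' @export
contingency_table <- function(records, row_factor, col_factor,
                              row_levels = NULL, col_levels = NULL,
                              drop_empty = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no records to tabulate")
  for (f in c(row_factor, col_factor)) {
    if (!f %in% names(records)) stop("records lack column: ", f)
  }
  r <- .as_declared_factor(records[[row_factor]], row_factor, row_levels)
  c_ <- .as_declared_factor(records[[col_factor]], col_factor, col_levels)
  if (anyNA(r) || anyNA(c_)) stop("missing values in '", row_factor, "' or '",
                                  col_factor, "'")
  tab <- table(r, c_, dnn = c(row_factor, col_factor))
  if (drop_empty) {
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  tab
}

.check_counts <- function(t) {
  t <- as.matrix(t)
  if (any(t < 0) || any(t != round(t))) stop("counts must be non-negative integers")
  if (sum(t) < 1) stop("empty contingency table")
  t
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic sum((O-E)^2/E) with expected counts from the
#' margins, no continuity correction, df = (r-1)(c-1), upper-tail p. Expected
#' counts below 5 raise a warning (the small-sample caveat) but never trigger
#' an automatic switch to an exact test.
#'
#' @param t count matrix or `table`, at least 2 x 2, no all-zero row/column.
#' @return object of class `aqua_test` with fields `method`
#'   (`"pearson_chi_square"`), `statistic`, `df`, `p_value`, `expected`,
#'   `table`.
#' @export
chi_square_test <- function(t) {
  t <- .check_counts(t)
  if (nrow(t) < 2L || ncol(t) < 2L) stop("chi-square test needs at least a 2x2 table")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    stop("degenerate margins: all-zero row or column")
  }
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  if (any(expected < 5)) {
    warning("expected count(s) below 5; chi-square approximation may be poor",
            call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
  structure(
    list(method = "pearson_chi_square",
         statistic = unname(res$statistic),
         df = unname(res$parameter),
         p_value = unname(res$p.value),
         expected = expected, table = t),
    class = "aqua_test"
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by the point-probability convention: the sum, over all
#' tables with the observed margins, of the hypergeometric probabilities not
#' exceeding that of the observed table (with a small relative tolerance for
#' ties).
#'
#' @param t 2 x 2 count matrix or `table`.
#' @return object of class `aqua_test` with `method = "fisher_exact_2x2"`,
#'   `p_value`, and `statistic`/`df` set to `NA` (the test has no statistic).
#' @export
fisher_exact_2x2 <- function(t) {
  t <- .check_counts(t)
  if (!all(dim(t) == c(2L, 2L))) {
    stop("fisher_exact_2x2 requires a 2x2 table; use chi_square_test for larger tables")
  }
  res <- stats::fisher.test(t)
  structure(
    list(method = "fisher_exact_2x2",
         statistic = NA_real_, df = NA_integer_,
         p_value = unname(res$p.value),
         odds_ratio = unname(res$estimate), table = t),
    class = "aqua_test"
  )
}

#' @export
print.aqua_test <- function(x, digits = 4, ...) {
  if (x$method == "pearson_chi_square") {
    cat(sprintf("Pearson chi-square: X2 = %.*g, df = %d, p = %.*g\n",
                digits, x$statistic, x$df, digits, x$p_value))
  } else {
    cat(sprintf("Fisher exact (2x2, two-sided): p = %.*g\n", digits, x$p_value))
  }
  invisible(x)
}

#' Compare a categorical characteristic between two groups
#'
#' Builds the characteristic x group table and dispatches as the analysis
#' convention prescribes: Fisher exact when the characteristic is binary
#' (2 x 2 table), Pearson chi-square otherwise. Levels of the characteristic
#' with zero count in both groups are dropped before testing.
#'
#' @param records data.frame of per-record metadata.
#' @param factor_name column holding the characteristic.
#' @param group column holding the binary grouping (e.g. phase, or
#'   high/low quality).
#' @param ... passed to [contingency_table()].
#' @return an `aqua_test`.
#' @export
compare_groups <- function(records, factor_name, group, ...) {
  tab <- contingency_table(records, factor_name, group, ...)
  if (ncol(tab) != 2L) stop("grouping variable must have exactly 2 observed levels")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) == 2L) fisher_exact_2x2(tab) else chi_square_test(tab)
}
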