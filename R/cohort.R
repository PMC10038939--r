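# Descriptive cohort outputs: quality distribution, element completeness,
# and characteristics tables with attached univariable tests.

#' Round half away from zero
#'
#' Printed percentages use commercial (half-up) rounding to one decimal, not
#' the round-half-even rule of [round()]. Exact unrounded values are retained
#' alongside in all machine-readable outputs.
#'
#' @param x numeric vector.
#' @param digits decimal places; default 1.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.pct <- function(n, denom) {
  list(pct = round_half_up(100 * n / denom, 1), exact = 100 * n / denom)
}

#' Reduce a multi-assessor table to one designated assessment per report
#'
#' Descriptive summaries are computed from a single assessment per report.
#' Which assessor's scores feed them is configurable; by default the
#' designated primary assessor is the first assessor id appearing in the
#' table (for prospectively scored cohorts, the blinded pre-review assessor).
#'
#' @param assessments long-format assessment table.
#' @param assessor assessor id to designate; default the first in the data.
#' @return data.frame with one row per report, in first-appearance report
#'   order.
#' @export
primary_assessments <- function(assessments, assessor = NULL) {
  df <- as.data.frame(assessments)
  if (is.null(assessor)) assessor <- df$assessor_id[1]
  if (!assessor %in% df$assessor_id) stop("no assessments by assessor: ", assessor)
  out <- df[df$assessor_id == assessor, , drop = FALSE]
  if (anyDuplicated(out$report_id)) stop("duplicate reports for assessor ", assessor)
  rownames(out) <- NULL
  out
}

#' Quality-category distribution of a cohort
#'
#' Counts and percentages of reports per quality category, plus the
#' high-quality (total >= 10) and low-quality shares.
#'
#' @param assessments one designated assessment per report (see
#'   [primary_assessments()]).
#' @param rubric an `aqua_rubric`.
#' @return object of class `aqua_quality_distribution`: list with
#'   `categories` (data.frame category/n/pct/pct_exact), `high_quality` and
#'   `low_quality` (n and pct each) and `n_reports`.
#' @export
quality_distribution <- function(assessments, rubric = default_rubric()) {
  df <- as.data.frame(assessments)
  if (anyDuplicated(df$report_id)) {
    stop("one assessment per report expected; use primary_assessments() first")
  }
  totals <- total_score(df, rubric)
  cat_ <- categorize(totals)
  n <- as.integer(table(cat_))
  denom <- length(totals)
  p <- .pct(n, denom)
  hi <- sum(is_high_quality(totals))
  hp <- .pct(hi, denom); lp <- .pct(denom - hi, denom)
  structure(
    list(categories = data.frame(category = levels(cat_), n = n,
                                 pct = p$pct, pct_exact = p$exact,
                                 stringsAsFactors = FALSE),
         high_quality = list(n = hi, pct = hp$pct, pct_exact = hp$exact),
         low_quality = list(n = denom - hi, pct = lp$pct, pct_exact = lp$exact),
         n_reports = denom),
    class = "aqua_quality_distribution"
  )
}

#' @export
print.aqua_quality_distribution <- function(x, ...) {
  cat("Quality of reports (N =", x$n_reports, ")\n")
  for (i in seq_len(nrow(x$categories))) {
    cat(sprintf("  %-10s %3d (%.1f%%)\n", x$categories$category[i],
                x$categories$n[i], x$categories$pct[i]))
  }
  cat(sprintf("  High quality (score >= 10): %d (%.1f%%)\n",
              x$high_quality$n, x$high_quality$pct))
  invisible(x)
}

#' Breakdown of incomplete rubric elements across a cohort
#'
#' For every rubric element, the number and percentage of reports scoring
#' below that element's maximum (not or only partially completed).
#'
#' @inheritParams quality_distribution
#' @return data.frame with columns `element_id`, `name`, `n_incomplete`,
#'   `pct`, `pct_exact`, in rubric order; class
#'   `aqua_completeness`.
#' @export
completeness_breakdown <- function(assessments, rubric = default_rubric()) {
  df <- as.data.frame(assessments)
  if (anyDuplicated(df$report_id)) {
    stop("one assessment per report expected; use primary_assessments() first")
  }
  inc <- .incomplete_matrix(df, rubric)
  n <- colSums(inc)
  p <- .pct(n, nrow(df))
  structure(
    data.frame(element_id = rubric$elements$element_id,
               name = rubric$elements$name,
               n_incomplete = as.integer(n),
               pct = p$pct, pct_exact = p$exact,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("aqua_completeness", "data.frame")
  )
}

#' Characteristics table with attached univariable tests
#'
#' Per characteristic: counts and within-group percentages of each level,
#' grouped by a binary variable (reporting phase or high/low quality), with
#' the dispatched test result ([compare_groups()]) attached per block.
#' Medication classes are counted per mention — a report contributes one
#' count per implicated class, possibly several — so that block's denominator
#' is the number of mentions, not reports.
#'
#' @param metadata data.frame, one row per report, with the grouping column
#'   and the characteristic columns; `medication_classes` may be a
#'   semicolon-separated string or a list column.
#' @param group grouping column name (`"phase"` or `"quality_group"`).
#' @param factors characteristic columns to tabulate; defaults to the
#'   standard report descriptors present in `metadata`.
#' @param medication_col name of the medication-class column, or `NULL` to
#'   skip; skipped silently when absent.
#' @return object of class `aqua_characteristics`: named list of blocks, each
#'   a list with `counts` (levels x groups matrix), `pct`, `pct_exact`,
#'   `denominators` (per group), and `test` (an `aqua_test`, or `NULL` with a
#'   warning when only one group is observed; the mention-level
#'   medication-class block carries its test for completeness, computed on
#'   mention counts).
#' @export
characteristics_table <- function(metadata, group,
                                  factors = NULL,
                                  medication_col = "medication_classes") {
  stopifnot(is.data.frame(metadata))
  if (!group %in% names(metadata)) stop("metadata lacks grouping column: ", group)
  if (is.null(factors)) {
    factors <- intersect(c("reporter_vocation", "reporting_unit",
                           "reaction_type", "severity"), names(metadata))
  }
  missing_meta <- setdiff(factors, names(metadata))
  if (length(missing_meta)) stop("metadata lacks column(s): ",
                                 paste(missing_meta, collapse = ", "))
  na_rows <- metadata$report_id[!stats::complete.cases(metadata[, c(group, factors)])]
  if (length(na_rows)) {
    stop("missing metadata for report(s): ", paste(na_rows, collapse = ", "))
  }
  g <- .as_declared_factor(metadata[[group]], group)
  g <- droplevels(g)
  single_group <- nlevels(g) < 2L
  if (single_group) {
    warning("only one group observed; counts reported without tests", call. = FALSE)
  }

  block_of <- function(values, gvec, name) {
    f <- .as_declared_factor(values, name)
    counts <- table(f, gvec, dnn = c(name, group))
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    denom <- colSums(counts)
    pct_exact <- sweep(100 * counts, 2, denom, "/")
    test <- NULL
    if (!single_group) {
      tab <- counts
      test <- if (nrow(tab) == 2L && ncol(tab) == 2L) fisher_exact_2x2(tab)
              else chi_square_test(tab)
    }
    list(counts = unclass(counts), pct = round_half_up(pct_exact, 1),
         pct_exact = unclass(pct_exact), denominators = denom, test = test)
  }

  blocks <- list()
  for (f in factors) blocks[[f]] <- block_of(metadata[[f]], g, f)

  if (!is.null(medication_col) && medication_col %in% names(metadata)) {
    cls <- metadata[[medication_col]]
    if (!is.list(cls)) cls <- strsplit(as.character(cls), ";", fixed = TRUE)
    cls <- lapply(cls, trimws)
    n_mentions <- lengths(cls)
    blocks[[medication_col]] <- block_of(
      unlist(cls), rep(g, n_mentions), medication_col)
  }
  structure(blocks, class = "aqua_characteristics", group = group)
}

#' @export
print.aqua_characteristics <- function(x, ...) {
  for (name in names(x)) {
    b <- x[[name]]
    cat(name, " (N = ", paste(b$denominators, collapse = " / "), ")",
        if (!is.null(b$test)) sprintf("  p = %.3g", b$test$p_value), "\n",
        sep = "")
    for (i in seq_len(nrow(b$counts))) {
      cells <- sprintf("%d (%.1f)", b$counts[i, ], b$pct[i, ])
      cat(sprintf("  %-50s %s\n", rownames(b$counts)[i],
                  paste(cells, collapse = "  ")))
    }
  }
  invisible(x)
}
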