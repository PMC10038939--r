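# CSV/JSON input-output for assessments and report metadata.

.assessment_cols <- function(rubric) {
  c("report_id", "assessor_id", rubric$elements$element_id)
}

#' Read an assessment CSV
#'
#' Schema: one row per (report, assessor) with columns `report_id`,
#' `assessor_id` and one integer column per rubric element, UTF-8 with a
#' header. Missing header columns are fatal. Rows failing validation (an
#' out-of-range score, a non-integer cell) are rejected with their file line
#' numbers: under `strict = TRUE` rejection is an error, otherwise the
#' offending rows are dropped with a warning and the run continues.
#'
#' @param path CSV path.
#' @param rubric an `aqua_rubric`.
#' @param strict abort on the first malformed row? Default FALSE.
#' @return an [as_assessments()] table; the dropped line numbers (if any) are
#'   attached as attribute `rejected_lines`.
#' @export
read_assessments <- function(path, rubric = default_rubric(), strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(report_id = "character",
                                       assessor_id = "character"))
  missing_cols <- setdiff(.assessment_cols(rubric), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no assessment rows in ", path)
  ok <- rep(TRUE, nrow(df))
  errs <- character(0)
  for (i in seq_len(nrow(df))) {
    e <- tryCatch({ validate_assessment(df[i, ], rubric); NULL },
                  error = function(e) conditionMessage(e))
    if (!is.null(e)) {
      ok[i] <- FALSE
      errs <- c(errs, sprintf("line %d: %s", i + 1L, e))  # +1 for the header
    }
  }
  if (length(errs)) {
    msg <- paste(errs, collapse = "\n  ")
    if (strict) stop("malformed assessment row(s):\n  ", msg)
    warning(length(errs), " row(s) rejected:\n  ", msg, call. = FALSE)
  }
  out <- as_assessments(df[ok, , drop = FALSE], rubric)
  attr(out, "rejected_lines") <- which(!ok) + 1L
  out
}

#' Write assessments to CSV
#'
#' Inverse of [read_assessments()]: `write_assessments` then
#' `read_assessments` is the identity on valid tables.
#'
#' @param x assessment table.
#' @param path output CSV path.
#' @param rubric an `aqua_rubric`.
#' @export
write_assessments <- function(x, path, rubric = default_rubric()) {
  df <- as.data.frame(x)[, .assessment_cols(rubric)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a report-metadata CSV
#'
#' Schema: `report_id`, `reporter_vocation`, `reporting_unit`,
#' `reaction_type`, `severity`, `phase`, `medication_classes`
#' (semicolon-separated mentions; a class may recur when several implicated
#' medications share it). Category values must belong to the declared levels
#' ([aqua_factor_levels()]).
#'
#' @param path CSV path.
#' @param check validate category levels? Default TRUE.
#' @return data.frame, one row per report.
#' @export
read_metadata <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(report_id = "character"))
  if (!"report_id" %in% names(df)) stop("missing required column: report_id")
  if (check) {
    lv <- aqua_factor_levels()
    for (f in intersect(names(lv), names(df))) {
      if (f == "medication_classes") next
      bad <- setdiff(unique(df[[f]]), lv[[f]])
      if (length(bad)) stop("unknown level(s) for '", f, "': ",
                            paste(bad, collapse = ", "))
    }
    if ("medication_classes" %in% names(df)) {
      mentions <- unlist(strsplit(df$medication_classes, ";", fixed = TRUE))
      bad <- setdiff(trimws(mentions), lv$medication_classes)
      if (length(bad)) stop("unknown medication class(es): ",
                            paste(bad, collapse = ", "))
    }
  }
  df
}

#' Write report metadata to CSV
#' @param x metadata data.frame.
#' @param path output CSV path.
#' @export
write_metadata <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' The packaged 70-report fixture cohort
#'
#' A fully synthetic reconstruction of the published 70-report reference
#' cohort (20 development-phase, 50 evaluation-phase reports): per-report
#' element scores from a designated primary assessor and categorical
#' metadata, constructed so that every published marginal count — the
#' quality-category distribution per phase, the per-element incompleteness
#' counts per phase, and every characteristic's phase and quality-group
#' cross-tabulation — is reproduced exactly. Individual rows are synthetic:
#' the real per-report data were never published. The published
#' medication-class totals column contains an internal inconsistency
#' (per-phase counts sum to 112 mentions but the totals column to 110); the
#' fixture follows the per-phase counts.
#'
#' @return list with `assessments` (70 rows, assessor `"primary"`) and
#'   `metadata` (70 rows, including `phase` and the derived `quality_group`).
#' @export
cohort_fixture <- function() {
  ext <- system.file("extdata", package = "aqua12")
  if (!nzchar(ext)) ext <- file.path("inst", "extdata")
  assessments <- read_assessments(file.path(ext, "cohort_fixture_scores.csv"))
  metadata <- read_metadata(file.path(ext, "cohort_fixture_metadata.csv"))
  metadata$quality_group <- ifelse(
    is_high_quality(total_score(as.data.frame(assessments))[
      match(metadata$report_id, assessments$report_id)]),
    "High", "Low")
  list(assessments = assessments, metadata = metadata)
}
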