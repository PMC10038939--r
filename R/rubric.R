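# AQUA-12 rubric: seven data elements, ordinal scores, total out of 12.

#' The AQUA-12 element identifiers, in rubric order
#'
#' @return Character vector of the seven element ids.
#' @export
aqua_elements <- function() {
  c("prev_adr_history", "actual_reaction", "key_events",
    "suspected_medications", "timeline", "management", "outcome_sequelae")
}

#' Construct a rubric definition
#'
#' A rubric is an ordered set of elements, each with an id, a display name
#' and a maximum ordinal score (1 or 2). The allowed scores for an element
#' are always the consecutive integers `0:max_score`.
#'
#' @param elements data.frame with columns `element_id`, `name`, `max_score`.
#' @return An object of class `aqua_rubric`: list with `elements` (the
#'   validated data.frame) and `total_max` (sum of element maxima).
#' @export
aqua_rubric <- function(elements) {
  stopifnot(is.data.frame(elements))
  req <- c("element_id", "name", "max_score")
  missing_cols <- setdiff(req, names(elements))
  if (length(missing_cols)) {
    stop("rubric definition lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  elements$element_id <- as.character(elements$element_id)
  elements$name <- as.character(elements$name)
  elements$max_score <- as.integer(elements$max_score)
  if (anyDuplicated(elements$element_id)) {
    stop("duplicate element_id in rubric")
  }
  if (!all(elements$max_score %in% c(1L, 2L))) {
    stop("element max_score must be 1 or 2")
  }
  structure(
    list(elements = elements[, req], total_max = sum(elements$max_score)),
    class = "aqua_rubric"
  )
}

#' Read a rubric definition from JSON
#'
#' The JSON file holds an ordered array of elements with fields `element_id`,
#' `name`, `allowed_scores` and `max_score`. `allowed_scores` must be the
#' consecutive integers from 0 to `max_score`.
#'
#' @param path path to a rubric JSON file.
#' @return An `aqua_rubric` object.
#' @export
read_rubric <- function(path) {
  if (!file.exists(path)) stop("rubric file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  el <- raw$elements
  if (is.null(el)) stop("rubric JSON must contain an 'elements' array")
  if (!is.null(el$allowed_scores)) {
    for (i in seq_len(nrow(el))) {
      expect <- 0:el$max_score[i]
      got <- sort(unlist(el$allowed_scores[i]))
      if (!identical(as.integer(got), as.integer(expect))) {
        stop("element '", el$element_id[i],
             "': allowed_scores must be 0..max_score")
      }
    }
  }
  aqua_rubric(el[, c("element_id", "name", "max_score")])
}

#' The default AQUA-12 rubric
#'
#' Seven elements in fixed order: previous ADR history, actual reaction,
#' description of key events, suspected medications, timeline relevant to the
#' ADR, management of reaction, and outcome/sequelae. The timeline and
#' management elements are scored 0-1; all others 0-2; total maximum 12.
#'
#' @return An `aqua_rubric` object.
#' @export
default_rubric <- function() {
  path <- system.file("extdata", "aqua12_rubric.json", package = "aqua12")
  if (!nzchar(path)) {
    # during development the package may not be installed yet
    path <- file.path("inst", "extdata", "aqua12_rubric.json")
  }
  read_rubric(path)
}

#' @export
print.aqua_rubric <- function(x, ...) {
  cat("AQUA rubric:", nrow(x$elements), "elements, total max", x$total_max, "\n")
  for (i in seq_len(nrow(x$elements))) {
    cat(sprintf("  %-22s (0-%d)  %s\n", x$elements$element_id[i],
                x$elements$max_score[i], x$elements$name[i]))
  }
  invisible(x)
}

# extract the element-score columns of an assessment data.frame, checking
# presence; internal
.element_scores <- function(a, rubric) {
  ids <- rubric$elements$element_id
  missing_el <- setdiff(ids, names(a))
  if (length(missing_el)) {
    stop("assessment is missing element(s): ", paste(missing_el, collapse = ", "))
  }
  a[ids]
}

#' Validate a single assessment against a rubric
#'
#' An assessment carries one assessor's element scores for one report. Every
#' rubric element must be present exactly once and every score must lie in
#' that element's allowed set (`0:max_score`). Elements recorded in the source
#' report as missing or "see medical records" are entered as score 0 by the
#' data-entry layer; absent columns are an error, never imputed.
#'
#' @param a named list or one-row data.frame with one integer score per
#'   element id (extra fields such as `report_id` are ignored).
#' @param rubric an `aqua_rubric`; defaults to [default_rubric()].
#' @return the validated scores as a named integer vector, invisibly usable
#'   downstream; errors name the offending element and value.
#' @export
validate_assessment <- function(a, rubric = default_rubric()) {
  scores <- .element_scores(as.list(a), rubric)
  out <- integer(0)
  for (i in seq_along(scores)) {
    id <- names(scores)[i]
    v <- scores[[i]]
    if (length(v) != 1L || is.na(v) || !is.finite(as.numeric(v)) ||
        as.numeric(v) != as.integer(v)) {
      stop("score for element '", id, "' must be a single integer, got: ",
           paste(format(v), collapse = ","))
    }
    v <- as.integer(v)
    mx <- rubric$elements$max_score[match(id, rubric$elements$element_id)]
    if (v < 0L || v > mx) {
      stop("score ", v, " not allowed for ", id, " (allowed 0..", mx, ")")
    }
    out[id] <- v
  }
  out
}

#' Total AQUA-12 score
#'
#' Arithmetic sum of the seven element scores; ranges 0 to 12 under the
#' default rubric.
#'
#' @param a a validated named score vector, or a data.frame of assessments
#'   with one column per element.
#' @param rubric an `aqua_rubric`.
#' @return integer vector of totals (length = rows of `a`).
#' @export
total_score <- function(a, rubric = default_rubric()) {
  ids <- rubric$elements$element_id
  if (is.data.frame(a)) {
    missing_el <- setdiff(ids, names(a))
    if (length(missing_el)) {
      stop("assessment is missing element(s): ", paste(missing_el, collapse = ", "))
    }
    as.integer(rowSums(a[, ids, drop = FALSE]))
  } else {
    as.integer(sum(unlist(.element_scores(as.list(a), rubric))))
  }
}

#' Quality category boundaries
#'
#' @return data.frame with columns `label`, `lo`, `hi`: Excellent = 12,
#'   Good = 10-11, Moderate = 8-9, Poor = 0-7. The ranges partition 0..12.
#' @export
quality_categories <- function() {
  data.frame(
    label = c("Excellent", "Good", "Moderate", "Poor"),
    lo = c(12L, 10L, 8L, 0L),
    hi = c(12L, 11L, 9L, 7L),
    stringsAsFactors = FALSE
  )
}

#' Map total scores to quality categories
#'
#' @param score integer vector of totals in \[0, 12\].
#' @return factor with levels Excellent, Good, Moderate, Poor.
#' @export
categorize <- function(score) {
  score <- .check_score_range(score)
  qc <- quality_categories()
  idx <- vapply(score, function(s) which(s >= qc$lo & s <= qc$hi), integer(1))
  factor(qc$label[idx], levels = qc$label)
}

#' High-quality threshold
#'
#' A report is high quality when its total score is at least 10 (category
#' Excellent or Good); below 10 it is low quality.
#'
#' @param score integer vector of totals in \[0, 12\].
#' @return logical vector.
#' @export
is_high_quality <- function(score) {
  score <- .check_score_range(score)
  score >= 10L
}

.check_score_range <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 12) ||
      any(score != as.integer(score))) {
    stop("total score must be an integer in [0, 12]")
  }
  as.integer(score)
}

#' Elements not or only partially completed
#'
#' Returns the element ids whose score falls below that element's maximum; a
#' partial score counts as incomplete. Empty exactly when the total is 12.
#'
#' @param a a single assessment (named scores, extra fields ignored).
#' @param rubric an `aqua_rubric`.
#' @return character vector of element ids (possibly empty).
#' @export
incomplete_elements <- function(a, rubric = default_rubric()) {
  scores <- validate_assessment(a, rubric)
  ids <- rubric$elements$element_id
  mx <- rubric$elements$max_score
  ids[scores[ids] < mx]
}

# logical matrix (reports x elements) of below-maximum scores; internal
.incomplete_matrix <- function(df, rubric) {
  ids <- rubric$elements$element_id
  mx <- rubric$elements$max_score
  m <- as.matrix(df[, ids, drop = FALSE])
  sweep(m, 2, mx, "<")
}

#' Validate a table of assessments
#'
#' Checks a long-format assessment table (one row per report x assessor)
#' against the rubric, row by row.
#'
#' @param df data.frame with columns `report_id`, `assessor_id` and one column
#'   per rubric element.
#' @param rubric an `aqua_rubric`.
#' @return `df` with class `aqua_assessments` and the rubric attached as an
#'   attribute; errors identify the first offending row.
#' @export
as_assessments <- function(df, rubric = default_rubric()) {
  stopifnot(is.data.frame(df))
  for (col in c("report_id", "assessor_id")) {
    if (!col %in% names(df)) stop("assessment table lacks column: ", col)
    df[[col]] <- as.character(df[[col]])
  }
  ids <- rubric$elements$element_id
  missing_el <- setdiff(ids, names(df))
  if (length(missing_el)) {
    stop("assessment table is missing element(s): ",
         paste(missing_el, collapse = ", "))
  }
  if (anyDuplicated(df[, c("report_id", "assessor_id")])) {
    stop("duplicate (report_id, assessor_id) rows in assessment table")
  }
  for (i in seq_len(nrow(df))) {
    tryCatch(validate_assessment(df[i, ], rubric),
             error = function(e) stop("row ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  }
  structure(df, class = c("aqua_assessments", "data.frame"), rubric = rubric)
}
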