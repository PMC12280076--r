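# Completeness metrics and the documentation-clarity (comprehension) rubric.

#' Proportion of required fields present
#'
#' A required field counts as present when and only when its column exists;
#' cell-level gaps are the missing-percentage metric's job, keeping the two
#' completeness metrics disjoint. The raw value is the presence fraction in
#' `[0, 1]`; missing field names are listed in params.
#'
#' @param data a [tabular_dataset()] with non-empty `required_fields`.
#' @return a [metric_result()]; larger is better.
#' @export
metric_required_fields <- function(data) {
  stopifnot(inherits(data, "tabular_dataset"))
  req <- data$required_fields
  if (length(req) == 0L) stop_smd("required_fields is empty")
  present <- req %in% names(data$data)
  metric_result("Proportion of Required Fields", mean(present),
                params = list(required = req,
                              missing_fields = req[!present]))
}

#' Percentage of missing cells
#'
#' `100 * missing cells / (rows * columns)`, with a per-column breakdown in
#' params. Both completeness proportions are invariant to row and column
#' order.
#'
#' @param data a non-empty [tabular_dataset()].
#' @return a [metric_result()] in percent; smaller is better.
#' @export
metric_missing_pct <- function(data) {
  stopifnot(inherits(data, "tabular_dataset"))
  df <- data$data
  if (nrow(df) < 1L || ncol(df) < 1L) stop_smd("table is empty")
  miss <- vapply(df, function(col) sum(is.na(col)), integer(1))
  raw <- 100 * sum(miss) / (nrow(df) * ncol(df))
  metric_result("Missing Data Percentage", raw,
                params = list(per_column_pct = as.list(100 * miss / nrow(df)),
                              cells = nrow(df) * ncol(df),
                              missing_cells = sum(miss)))
}

#' Construct a documentation-clarity rubric
#'
#' Eight required items covering how clearly the data-generation process is
#' documented; each is scored 0 (absent), 1 (partial) or 2 (clear) by a
#' human rater. The metric quantifies the rubric -- it does not read
#' documents -- so the rater's role should be recorded alongside.
#'
#' @param scores named numeric vector with values in `{0, 1, 2}`; names
#'   must include all of `generation_method`, `parameters_listed`,
#'   `version_history`, `license`, `contact`, `limitations`,
#'   `preprocessing`, `intended_use`.
#' @param rater free-text description of who scored the rubric.
#' @return an object of class `clarity_rubric`.
#' @export
clarity_rubric <- function(scores, rater = "unspecified") {
  required <- c("generation_method", "parameters_listed", "version_history",
                "license", "contact", "limitations", "preprocessing",
                "intended_use")
  missing <- setdiff(required, names(scores))
  if (length(missing)) {
    stop_smd("rubric missing required items: %s", paste(missing, collapse = ", "))
  }
  if (!all(scores %in% c(0, 1, 2))) stop_smd("rubric scores must be 0, 1 or 2")
  structure(list(scores = scores[unique(c(required, names(scores)))],
                 rater = rater),
            class = "clarity_rubric")
}

#' Documentation clarity score
#'
#' Sum of rubric item scores divided by twice the item count, in `[0, 1]`.
#' Per-item scores and the human-rater provenance are retained in params.
#'
#' @param rubric a [clarity_rubric()].
#' @return a [metric_result()]; larger is better.
#' @export
metric_doc_clarity <- function(rubric) {
  stopifnot(inherits(rubric, "clarity_rubric"))
  s <- rubric$scores
  metric_result("Documentation Clarity Score", sum(s) / (2 * length(s)),
                params = list(items = as.list(s), rater = rubric$rater,
                              origin = "human-assigned rubric"))
}

#' Record a human completeness rating on a defined scale
#'
#' Stores a human 1-to-`scale_max` completeness rating and normalizes it
#' linearly onto `[0, 1]` as `(value - 1) / (scale_max - 1)`.
#'
#' @param scale_value the rating, in `[1, scale_max]`.
#' @param scale_max top of the scale (default 10).
#' @return a [metric_result()] with `normalized` set.
#' @export
record_completeness_rating <- function(scale_value, scale_max = 10) {
  if (scale_value < 1 || scale_value > scale_max) {
    stop_smd("rating must lie in [1, %g]", scale_max)
  }
  metric_result("Completeness Rating", scale_value,
                normalized = (scale_value - 1) / (scale_max - 1),
                params = list(scale_max = scale_max,
                              origin = "human-assigned rating"))
}
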