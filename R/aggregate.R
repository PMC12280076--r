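# Direction-aware normalization, weighted aggregation, and threshold
# classification of criterion scores.

#' Construct a calibration entry for one metric
#'
#' Maps a raw metric value onto the `[0, 1]` score scale. For maximize /
#' minimize metrics, `best` is the raw value mapping to score 1 and
#' `worst` the value mapping to 0. For band metrics, the score is 1 inside
#' `[band_lo, band_hi]` and decays linearly to 0 over `decay_width` outside
#' the band. Anchors may come from configuration (clinical knowledge) or be
#' derived from a reference dataset (see [calibrate_from_reference()]).
#'
#' @param best,worst raw anchor values (must differ).
#' @param band_lo,band_hi,decay_width band parameters.
#' @param source `"configured"` or `"reference-derived"`.
#' @return an object of class `calibration_entry`.
#' @export
calibration_entry <- function(best = NULL, worst = NULL, band_lo = NULL,
                              band_hi = NULL, decay_width = NULL,
                              source = "configured") {
  if (!is.null(best) && !is.null(worst) && best == worst) {
    stop_smd("calibration needs best != worst")
  }
  if (!is.null(band_lo) && !is.null(band_hi)) {
    if (band_lo > band_hi) stop_smd("band needs band_lo <= band_hi")
    if (is.null(decay_width) || decay_width <= 0) {
      stop_smd("band calibration needs decay_width > 0")
    }
  }
  structure(list(best = best, worst = worst, band_lo = band_lo,
                 band_hi = band_hi, decay_width = decay_width,
                 source = source),
            class = "calibration_entry")
}

#' Normalize a raw metric value onto [0, 1]
#'
#' Maximize: `clip((v - worst) / (best - worst), 0, 1)`; minimize:
#' `clip((worst - v) / (worst - best), 0, 1)`; band: 1 inside the band,
#' linear decay to 0 over `decay_width` outside it. Metrics whose direction
#' is statistical significance are reported raw and never normalized.
#' Normalization is monotone in the raw value for the monotone directions.
#'
#' @param result a [metric_result()].
#' @param spec the metric's [metric_spec()] (supplies the direction); a
#'   `direction` string is also accepted.
#' @param cal a [calibration_entry()].
#' @return the result with `normalized` set (untouched for stat_sig).
#' @export
normalize_metric <- function(result, spec, cal) {
  stopifnot(inherits(result, "metric_result"))
  direction <- if (inherits(spec, "metric_spec")) spec$direction else
    match.arg(spec, c("maximize", "minimize", "band", "stat_sig"))
  if (direction == "stat_sig") return(result)
  stopifnot(inherits(cal, "calibration_entry"))
  v <- result$raw_value
  score <- if (direction == "band") {
    if (is.null(cal$band_lo)) stop_smd("band metric needs band calibration")
    if (v >= cal$band_lo && v <= cal$band_hi) {
      1
    } else {
      excess <- if (v < cal$band_lo) cal$band_lo - v else v - cal$band_hi
      max(0, 1 - excess / cal$decay_width)
    }
  } else {
    if (is.null(cal$best) || is.null(cal$worst)) {
      stop_smd("metric '%s' lacks best/worst calibration", result$metric)
    }
    if (direction == "maximize") {
      (v - cal$worst) / (cal$best - cal$worst)
    } else {
      (cal$worst - v) / (cal$worst - cal$best)
    }
  }
  result$normalized <- max(0, min(1, score))
  result$params$calibration <- list(direction = direction,
                                    best = cal$best, worst = cal$worst,
                                    band_lo = cal$band_lo, band_hi = cal$band_hi,
                                    decay_width = cal$decay_width,
                                    source = cal$source)
  result
}

#' Derive a "best" calibration anchor from a reference split-half baseline
#'
#' Operationalizes reference-derived thresholds reproducibly: the reference
#' is split in half by a seeded permutation, the binary metric is evaluated
#' half versus half, and that self-congruence value becomes the `best`
#' anchor (a synthetic dataset cannot be expected to align with the
#' reference better than the reference aligns with itself). `worst` stays
#' configured.
#'
#' @param metric_fn binary metric function `(reference, synthetic)`.
#' @param reference a [feature_matrix()] with `n >= 4`.
#' @param worst configured worst anchor.
#' @param seed integer seed for the split.
#' @return a [calibration_entry()] with `source = "reference-derived"`.
#' @export
calibrate_from_reference <- function(metric_fn, reference, worst, seed = 1L) {
  stopifnot(inherits(reference, "feature_matrix"))
  n <- nrow(reference$values)
  if (n < 4L) stop_smd("split-half calibration needs n >= 4")
  idx <- with_seed(seed, sample.int(n))
  half <- floor(n / 2)
  a <- feature_matrix(reference$values[idx[seq_len(half)], , drop = FALSE])
  b <- feature_matrix(reference$values[idx[(half + 1):n], , drop = FALSE])
  best <- metric_fn(a, b)$raw_value
  if (best == worst) stop_smd("split-half anchor equals worst; configure best explicitly")
  calibration_entry(best = best, worst = worst, source = "reference-derived")
}

#' Aggregate normalized metric results into a criterion score
#'
#' Weighted arithmetic mean or weighted geometric mean of the member
#' normalized scores (equal weights by default; weights are renormalized to
#' sum to 1). A zero member annihilates the geometric mean. Member results
#' are retained on the score -- raw values and aggregates are always
#' reported together.
#'
#' @param criterion criterion key (one of [smd_criteria()]).
#' @param results list of normalized [metric_result()] objects.
#' @param weights optional non-negative numeric vector, one per result.
#' @param method `"arithmetic"` or `"geometric"`.
#' @param thresholds passed to [classify_score()].
#' @return an object of class `criterion_score`.
#' @export
aggregate_criterion <- function(criterion, results, weights = NULL,
                                method = c("arithmetic", "geometric"),
                                thresholds = c(good_min = 0.80,
                                               moderate_min = 0.70)) {
  method <- match.arg(method)
  criterion <- match.arg(tolower(criterion), smd_criteria())
  if (length(results) == 0L) stop_smd("no metric results to aggregate")
  scores <- vapply(results, function(r) {
    stopifnot(inherits(r, "metric_result"))
    if (is.null(r$normalized)) {
      stop_smd("metric '%s' is not normalized", r$metric)
    }
    r$normalized
  }, numeric(1))
  m <- length(scores)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop_smd("weights must match results")
  if (any(weights < 0) || sum(weights) == 0) {
    stop_smd("weights must be non-negative and not all zero")
  }
  weights <- weights / sum(weights)
  score <- if (method == "arithmetic") {
    sum(weights * scores)
  } else {
    if (any(scores == 0)) 0 else exp(sum(weights * log(scores)))
  }
  score <- max(0, min(1, score))
  structure(
    list(criterion = criterion, score = score,
         label = classify_score(score, thresholds["good_min"],
                                thresholds["moderate_min"]),
         weights = weights, method = method, members = results),
    class = "criterion_score"
  )
}

#' @export
print.criterion_score <- function(x, ...) {
  cat(sprintf("<criterion_score %s: %.3f (%s), %d metrics>\n",
              x$criterion, x$score, x$label, length(x$members)))
  invisible(x)
}

#' Classify an aggregated score as good / moderate / low
#'
#' `good` when `score >= good_min`, `moderate` when
#' `moderate_min <= score < good_min`, `low` below. Defaults 0.80 / 0.70
#' follow the worked coverage example; thresholds vary with the clinical
#' application and are always config-overridable.
#'
#' @param score aggregated score in `[0, 1]`.
#' @param good_min,moderate_min thresholds with
#'   `0 <= moderate_min < good_min <= 1`.
#' @return `"good"`, `"moderate"` or `"low"`.
#' @export
#' @examples
#' classify_score(0.82) # "good"
#' classify_score(0.70) # "moderate"
#' classify_score(0.69) # "low"
classify_score <- function(score, good_min = 0.80, moderate_min = 0.70) {
  good_min <- as.numeric(good_min); moderate_min <- as.numeric(moderate_min)
  if (!(moderate_min < good_min) || good_min > 1 || moderate_min < 0) {
    stop_smd("thresholds must satisfy 0 <= moderate_min < good_min <= 1")
  }
  if (score >= good_min) "good"
  else if (score >= moderate_min) "moderate"
  else "low"
}
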