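# Declarative constraint engine and the constraint-adherence metrics.

#' Construct a constraint specification
#'
#' Declarative clinical/technical validity rule evaluated per sample.
#' Three kinds are supported:
#' * `interval`: `lo <= target <= hi` (one bound may be infinite, not both);
#' * `category_set`: target value must be one of `allowed`;
#' * `implication`: when the antecedent holds, the consequent must hold;
#'   antecedent and consequent are each `(feature, value)` for a category
#'   match or `(feature, lo, hi)` for an interval.
#'
#' @param id unique identifier.
#' @param target feature/column name the rule applies to (ignored for
#'   implications, which name their own features).
#' @param kind `"interval"`, `"category_set"` or `"implication"`.
#' @param lo,hi interval bounds in units of the target.
#' @param allowed character vector of allowed categories.
#' @param antecedent,consequent lists with fields `feature` and either
#'   `value` or `lo`/`hi`.
#' @return an object of class `constraint_spec`.
#' @export
#' @examples
#' constraint_spec("hb-anemia", kind = "implication",
#'   antecedent = list(feature = "condition", value = "anemia"),
#'   consequent = list(feature = "hemoglobin", lo = 0, hi = 12))
constraint_spec <- function(id, target = NULL,
                            kind = c("interval", "category_set", "implication"),
                            lo = -Inf, hi = Inf, allowed = NULL,
                            antecedent = NULL, consequent = NULL) {
  kind <- match.arg(kind)
  if (kind == "interval") {
    if (is.null(target)) stop_smd("interval constraint needs a target")
    if (lo > hi) stop_smd("interval needs lo <= hi")
    if (!is.finite(lo) && !is.finite(hi)) {
      stop_smd("interval needs at least one finite bound")
    }
  } else if (kind == "category_set") {
    if (is.null(target)) stop_smd("category_set constraint needs a target")
    if (is.null(allowed) || length(allowed) == 0L) {
      stop_smd("category_set needs a non-empty allowed set")
    }
  } else {
    check_part <- function(p, label) {
      if (is.null(p$feature)) stop_smd("implication %s needs a feature", label)
      if (is.null(p$value) && is.null(p$lo) && is.null(p$hi)) {
        stop_smd("implication %s needs a value or an interval", label)
      }
    }
    check_part(antecedent, "antecedent")
    check_part(consequent, "consequent")
  }
  structure(
    list(id = id, target = target, kind = kind, lo = lo, hi = hi,
         allowed = allowed, antecedent = antecedent, consequent = consequent),
    class = "constraint_spec"
  )
}

# Resolve a named column/feature against either container; returns a vector
# (numeric or character) possibly holding NA for tabular missing cells.
resolve_target <- function(data, name) {
  if (inherits(data, "feature_matrix")) {
    nm <- data$feature_names %||% paste0("f", seq_len(ncol(data$values)))
    j <- match(name, nm)
    if (is.na(j)) stop_smd("target '%s' not found among features", name)
    data$values[, j]
  } else if (inherits(data, "tabular_dataset")) {
    if (!name %in% names(data$data)) {
      stop_smd("target '%s' not found among columns", name)
    }
    data$data[[name]]
  } else {
    stop_smd("constraints evaluate on a feature_matrix or tabular_dataset")
  }
}

# Per-sample truth of a (feature, value-or-interval) implication part.
# Returns list(holds = logical, missing = logical).
eval_part <- function(data, part) {
  x <- resolve_target(data, part$feature)
  miss <- is.na(x)
  if (!is.null(part$value)) {
    holds <- !miss & as.character(x) == as.character(part$value)
  } else {
    lo <- part$lo %||% -Inf; hi <- part$hi %||% Inf
    holds <- !miss & suppressWarnings(as.numeric(x)) >= lo &
      suppressWarnings(as.numeric(x)) <= hi
  }
  holds[miss] <- FALSE
  list(holds = holds, missing = miss)
}

#' Evaluate constraints against a dataset
#'
#' Exact per-sample evaluation of every constraint. Interval violation
#' depth is `max(lo - x, x - hi, 0)` in units of the target. Implications
#' are violated when the antecedent holds and the consequent fails. Missing
#' values (tabular data) violate any constraint on that field -- clinical
#' constraints fail closed -- and the violation is flagged missing-driven.
#'
#' @param data a [feature_matrix()] or [tabular_dataset()].
#' @param specs list of [constraint_spec()] objects.
#' @return an object of class `violation_matrix` with logical `violated`
#'   (n x n_constraints), numeric `depth` (interval rules only), logical
#'   `missing_driven`, and the spec list.
#' @export
evaluate_constraints <- function(data, specs) {
  if (inherits(specs, "constraint_spec")) specs <- list(specs)
  n <- if (inherits(data, "feature_matrix")) nrow(data$values)
       else if (inherits(data, "tabular_dataset")) nrow(data$data)
       else stop_smd("constraints evaluate on a feature_matrix or tabular_dataset")
  m <- length(specs)
  violated <- matrix(FALSE, n, m)
  depth <- matrix(0, n, m)
  missing_driven <- matrix(FALSE, n, m)
  is_interval <- logical(m)
  ids <- character(m)
  for (j in seq_len(m)) {
    sp <- specs[[j]]
    stopifnot(inherits(sp, "constraint_spec"))
    ids[j] <- sp$id
    if (sp$kind == "interval") {
      is_interval[j] <- TRUE
      x <- suppressWarnings(as.numeric(resolve_target(data, sp$target)))
      miss <- is.na(x)
      dep <- pmax(sp$lo - x, x - sp$hi, 0)
      dep[miss] <- NA
      violated[, j] <- miss | (dep > 0)
      depth[, j] <- ifelse(miss, 0, dep)
      missing_driven[, j] <- miss
    } else if (sp$kind == "category_set") {
      x <- resolve_target(data, sp$target)
      miss <- is.na(x)
      violated[, j] <- miss | !(as.character(x) %in% sp$allowed)
      missing_driven[, j] <- miss
    } else {
      ant <- eval_part(data, sp$antecedent)
      con <- eval_part(data, sp$consequent)
      violated[, j] <- ant$holds & !con$holds
      missing_driven[, j] <- ant$holds & con$missing
    }
  }
  colnames(violated) <- colnames(depth) <- colnames(missing_driven) <- ids
  structure(
    list(violated = violated, depth = depth, missing_driven = missing_driven,
         is_interval = is_interval, specs = specs, n = n),
    class = "violation_matrix"
  )
}

#' @export
print.violation_matrix <- function(x, ...) {
  cat(sprintf("<violation_matrix: %d samples x %d constraints, %d violating samples>\n",
              x$n, ncol(x$violated), sum(rowSums(x$violated) > 0)))
  invisible(x)
}

#' Constraint violation rate
#'
#' Fraction of samples violating at least one constraint, in `[0, 1]`.
#' Zero constraints mean vacuous satisfaction (rate 0). Per-constraint
#' rates are reported alongside in params (dual reporting).
#'
#' @param vm a [evaluate_constraints()] result.
#' @return a [metric_result()]; smaller is better.
#' @export
metric_violation_rate <- function(vm) {
  stopifnot(inherits(vm, "violation_matrix"))
  if (vm$n < 1L) stop_smd("violation matrix has no samples")
  if (ncol(vm$violated) == 0L) {
    return(metric_result("Constraint Violation Rate", 0,
                         params = list(n_constraints = 0L)))
  }
  rate <- mean(rowSums(vm$violated) > 0)
  per_constraint <- colMeans(vm$violated)
  metric_result("Constraint Violation Rate", rate,
                params = list(per_constraint = as.list(per_constraint),
                              n_constraints = ncol(vm$violated),
                              missing_driven_rate = mean(rowSums(vm$missing_driven) > 0)))
}

#' Mean distance past constraint boundaries
#'
#' Mean violation depth over all (sample, interval-constraint) pairs, with
#' satisfied pairs contributing 0; units of the constrained targets. Params
#' add the mean positive margin `min(x - lo, hi - x)` over satisfied pairs,
#' showing how close satisfied samples sit to their boundaries.
#'
#' @param vm a [evaluate_constraints()] result containing at least one
#'   interval constraint.
#' @param data the dataset the matrix was computed on (needed for margins).
#' @return a [metric_result()]; smaller is better.
#' @export
metric_boundary_distance <- function(vm, data = NULL) {
  stopifnot(inherits(vm, "violation_matrix"))
  if (!any(vm$is_interval)) stop_smd("no interval constraints present")
  cols <- which(vm$is_interval)
  depths <- vm$depth[, cols, drop = FALSE]
  raw <- mean(depths)
  margin <- NA_real_
  if (!is.null(data)) {
    margins <- c()
    for (j in cols) {
      sp <- vm$specs[[j]]
      x <- suppressWarnings(as.numeric(resolve_target(data, sp$target)))
      sat <- !vm$violated[, j] & !is.na(x)
      if (any(sat)) margins <- c(margins, pmin(x[sat] - sp$lo, sp$hi - x[sat]))
    }
    if (length(margins)) margin <- mean(margins)
  }
  metric_result("Distance to Constraint Boundary", raw,
                params = list(n_interval_constraints = length(cols),
                              mean_margin_satisfied = margin))
}

#' Mean distance to the nearest invalid exemplar
#'
#' Per synthetic sample, the Euclidean distance to its nearest known-invalid
#' exemplar; the raw value is the mean and params carry the minimum. Larger
#' distances mean the synthetic data stays away from known-invalid regions,
#' so the default normalization direction is maximize (config-overridable);
#' the registry row keeps the printed minimize direction and the divergence
#' is recorded in params.
#'
#' @param synthetic a [feature_matrix()].
#' @param invalid_exemplars a non-empty [feature_matrix()] of invalid
#'   points with equal `d`.
#' @return a [metric_result()].
#' @export
metric_nearest_invalid <- function(synthetic, invalid_exemplars) {
  stopifnot(inherits(synthetic, "feature_matrix"),
            inherits(invalid_exemplars, "feature_matrix"))
  S <- synthetic$values; V <- invalid_exemplars$values
  if (ncol(S) != ncol(V)) stop_smd("dimension mismatch")
  if (nrow(V) < 1L) stop_smd("invalid exemplar set is empty")
  D <- cross_dist(S, V)
  nearest <- apply(D, 1, min)
  metric_result("Nearest Invalid Datapoint", mean(nearest),
                params = list(min_distance = min(nearest),
                              n_exemplars = nrow(V),
                              default_normalization_direction = "maximize",
                              registry_direction = "minimize"))
}
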