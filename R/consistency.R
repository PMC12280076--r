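# Stability of quality metrics across subgroups or time slices.

# Split a feature_matrix by its subgroup labels, preserving order of first
# appearance.
split_subgroups <- function(fm) {
  if (is.null(fm$subgroups)) stop_smd("subgroup labels are required")
  labels <- unique(fm$subgroups)
  stats::setNames(lapply(labels, function(g) {
    select_local(fm, fm$subgroups == g)
  }), labels)
}

#' Evaluate a metric once per subgroup
#'
#' Wraps any metric function and evaluates it within each subgroup of the
#' synthetic data; binary metrics pair each synthetic subgroup with the
#' like-labelled reference subgroup. The raw value is the unweighted mean
#' of the subgroup values and `per_subgroup` holds the full table, which
#' is what the dispersion and ANOVA consistency metrics consume. Subgroups
#' also serve as time slices: temporal consistency is the same machinery
#' with slice labels.
#'
#' @param metric_fn function taking (`synthetic`) or
#'   (`reference`, `synthetic`) feature matrices and returning a
#'   [metric_result()].
#' @param synthetic a [feature_matrix()] with subgroup labels.
#' @param reference optional [feature_matrix()] with subgroup labels
#'   (required when `metric_fn` is binary).
#' @param binary logical; does `metric_fn` take a reference first?
#' @param metric_name name recorded on the result.
#' @return a [metric_result()] with `per_subgroup` populated.
#' @export
per_subgroup_metric <- function(metric_fn, synthetic, reference = NULL,
                                binary = !is.null(reference),
                                metric_name = "per-subgroup metric") {
  syn_groups <- split_subgroups(synthetic)
  ref_groups <- NULL
  if (binary) {
    if (is.null(reference)) stop_smd("binary metric requires a reference")
    ref_groups <- split_subgroups(reference)
    unmatched <- setdiff(names(syn_groups), names(ref_groups))
    if (length(unmatched)) {
      stop_smd("no reference subgroup for label(s): %s",
               paste(unmatched, collapse = ", "))
    }
  }
  vals <- vapply(names(syn_groups), function(g) {
    res <- if (binary) metric_fn(ref_groups[[g]], syn_groups[[g]])
           else metric_fn(syn_groups[[g]])
    res$raw_value
  }, numeric(1))
  metric_result(metric_name, mean(vals), per_subgroup = vals,
                params = list(n_subgroups = length(vals),
                              aggregation = "unweighted mean"))
}

#' Dispersion of per-subgroup metric values
#'
#' `kind = "variance"` is the population variance (divide by m) of the m
#' subgroup values -- the subgroups are the entire population of interest,
#' not a sample. `kind = "maxmin"` is the max-minus-min spread. Both are 0
#' exactly when all subgroup values agree.
#'
#' @param values numeric vector of per-subgroup metric values (m >= 2),
#'   or a [metric_result()] with `per_subgroup` set.
#' @param kind `"variance"` or `"maxmin"`.
#' @return a [metric_result()]; smaller is better.
#' @export
metric_subgroup_dispersion <- function(values, kind = c("variance", "maxmin")) {
  kind <- match.arg(kind)
  if (inherits(values, "metric_result")) values <- values$per_subgroup
  values <- as.numeric(values)
  if (length(values) < 2L) stop_smd("dispersion needs >= 2 subgroup values")
  if (kind == "variance") {
    m <- length(values)
    raw <- sum((values - mean(values))^2) / m
    metric_result("Subgroup Variance", raw,
                  params = list(convention = "population (divide by m)",
                                m = m))
  } else {
    metric_result("Maximum-Minimum Difference", max(values) - min(values),
                  params = list(m = length(values)))
  }
}

# Closed-form one-way ANOVA from a list of replicate vectors; returns F,
# p, and degrees of freedom. Cross-checked against stats::anova(lm()) in
# the test suite.
oneway_f <- function(groups) {
  k <- length(groups)
  n_i <- lengths(groups)
  N <- sum(n_i)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n_i * means) / N
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    return(list(F = NA_real_, p = NA_real_, df1 = df1, df2 = df2,
                assessable = FALSE))
  }
  if (ssw == 0) {
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2, assessable = TRUE))
  }
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, assessable = TRUE)
}

#' One-way ANOVA of a metric across subgroups via bootstrap replicates
#'
#' A metric yields a single number per subgroup, so significance testing
#' needs replicates: `B` seeded within-subgroup bootstrap resamples (with
#' replacement) produce `B` replicate metric values per subgroup, and a
#' one-way ANOVA across subgroups is run on them. Because all `B`
#' replicates of a subgroup re-draw the same sample, the textbook
#' between-group mean square is inflated by a factor of `B`; the reported F
#' divides it out, giving a calibrated test (the uncorrected replicate F is
#' kept in params). The raw value is the corrected F statistic; the
#' p-value and degrees of freedom are in params. When every
#' replicate is identical across groups (zero within- and between-group
#' variance) the result is flagged not assessable rather than reported as
#' a number.
#'
#' @param metric_fn as in [per_subgroup_metric()].
#' @param synthetic a [feature_matrix()] with subgroup labels (each
#'   subgroup needs `n >= 2`).
#' @param reference optional [feature_matrix()] with subgroup labels.
#' @param binary logical; does `metric_fn` take a reference first?
#' @param B bootstrap replicates per subgroup (>= 2).
#' @param seed integer seed for the resampling.
#' @return a [metric_result()]; direction is statistical significance, not
#'   maximize/minimize, so it is reported and never normalized.
#' @export
metric_subgroup_anova <- function(metric_fn, synthetic, reference = NULL,
                                  binary = !is.null(reference), B = 100L,
                                  seed = 1L) {
  B <- as.integer(B)
  if (B < 2L) stop_smd("B must be >= 2")
  syn_groups <- split_subgroups(synthetic)
  if (length(syn_groups) < 2L) stop_smd("ANOVA needs >= 2 subgroups")
  ref_groups <- if (binary) split_subgroups(reference) else NULL
  small <- names(syn_groups)[vapply(syn_groups, function(g) nrow(g$values),
                                    integer(1)) < 2L]
  if (length(small)) stop_smd("subgroup(s) too small to bootstrap: %s",
                              paste(small, collapse = ", "))
  replicates <- with_seed(seed, {
    lapply(names(syn_groups), function(g) {
      syn <- syn_groups[[g]]
      n <- nrow(syn$values)
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        boot <- feature_matrix(syn$values[idx, , drop = FALSE])
        res <- if (binary) metric_fn(ref_groups[[g]], boot)
               else metric_fn(boot)
        res$raw_value
      }, numeric(1))
    })
  })
  names(replicates) <- names(syn_groups)
  av <- oneway_f(replicates)
  # Bootstrap replicates are B re-draws of the SAME subgroup sample, so the
  # textbook between-group mean square is inflated by a factor of B (each
  # subgroup mean is counted B times against a within-group spread that
  # estimates the metric's sampling variance once). Dividing F by B restores
  # a calibrated test: under the null E[F] ~ 1 and p-values are honest.
  F_corr <- if (av$assessable && is.finite(av$F)) av$F / B else av$F
  p_corr <- if (av$assessable && is.finite(F_corr)) {
    stats::pf(F_corr, av$df1, av$df2, lower.tail = FALSE)
  } else {
    av$p
  }
  metric_result("Analysis of Variance",
                if (av$assessable) F_corr else NA_real_,
                params = list(p_value = p_corr, df1 = av$df1, df2 = av$df2,
                              replicate_F = av$F, B = B, seed = seed,
                              assessable = av$assessable,
                              correction = "between-group mean square divided by B",
                              replication = "within-subgroup bootstrap"))
}
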