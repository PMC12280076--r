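# Privacy-compliance metrics: (k, l, t) anonymity profile, declared DP
# budget, and a nearest-record re-identification proxy.

#' Anonymity profile (k, l, t) of a tabular dataset
#'
#' Groups rows into equivalence classes of identical quasi-identifier
#' tuples, then reports: `k` = minimum class size, `l` = minimum number of
#' distinct sensitive values within a class, and `t` = maximum over classes
#' of the distance between the class's sensitive-value distribution and the
#' global one. The ground distance is total variation for categorical
#' sensitive attributes and 1-D Wasserstein on rank-normalized values
#' (range `[0, 1]`) for numeric ones, so `t` is always in `[0, 1]`. Rows
#' with missing quasi-identifier values are excluded and counted in params.
#'
#' @param data a [tabular_dataset()] with non-empty `quasi_identifiers`;
#'   `sensitive_attribute` must be set for l and t.
#' @return a [metric_result()] whose raw value is `k`; the full
#'   [anonymity_profile()] and `l`, `t` live in params.
#' @export
metric_anonymity_profile <- function(data) {
  stopifnot(inherits(data, "tabular_dataset"))
  qi <- data$quasi_identifiers
  if (length(qi) == 0L) stop_smd("quasi_identifiers must be non-empty")
  df <- data$data
  qi_complete <- stats::complete.cases(df[, qi, drop = FALSE])
  n_excluded <- sum(!qi_complete)
  df <- df[qi_complete, , drop = FALSE]
  if (nrow(df) == 0L) stop_smd("no rows with complete quasi-identifiers remain")
  key <- do.call(paste, c(lapply(df[, qi, drop = FALSE], as.character),
                          sep = "\r"))
  classes <- split(seq_len(nrow(df)), key)
  k <- min(lengths(classes))
  l <- NA_integer_; t <- NA_real_
  sens <- data$sensitive_attribute
  if (!is.null(sens)) {
    s_all <- df[[sens]]
    keep <- !is.na(s_all)
    numeric_sens <- data$column_kinds[[sens]] == "numeric"
    if (numeric_sens) {
      # rank-normalize onto [0,1] using the global ordering
      x <- as.numeric(s_all)
      r <- rank(x, ties.method = "average", na.last = "keep")
      u <- if (sum(keep) > 1L) (r - 1) / (sum(keep) - 1) else r * 0
    }
    per_class <- vapply(classes, function(idx) {
      s <- s_all[idx]; s <- s[!is.na(s)]
      length(unique(s))
    }, integer(1))
    l <- min(per_class)
    t <- max(vapply(classes, function(idx) {
      if (numeric_sens) {
        cls <- u[idx]; cls <- cls[!is.na(cls)]
        glob <- u[keep]
        if (length(cls) == 0L) return(0)
        wasserstein1d(cls, glob)
      } else {
        cls <- as.character(s_all[idx]); cls <- cls[!is.na(cls)]
        glob <- as.character(s_all[keep])
        if (length(cls) == 0L) return(0)
        levs <- unique(glob)
        p <- table(factor(cls, levels = levs)) / length(cls)
        q <- table(factor(glob, levels = levs)) / length(glob)
        sum(abs(p - q)) / 2
      }
    }, numeric(1)))
    t <- min(max(t, 0), 1)
  }
  profile <- anonymity_profile(k, l = if (is.na(l)) 1L else min(l, k),
                               t = if (is.na(t)) 0 else t)
  metric_result("K-Anonymity Level", k,
                params = list(l = l, t = t, profile = profile,
                              n_classes = length(classes),
                              rows_excluded_missing_qi = n_excluded,
                              t_ground_distance = if (is.null(sens)) NA_character_
                                else if (numeric_sens) "rank-normalized Wasserstein"
                                else "total variation"))
}

#' Record a declared differential-privacy budget
#'
#' Validates and stores the declared (epsilon, delta, mechanism) of the
#' generation process. The raw value is epsilon. This is a declared,
#' validated attribute of the pipeline -- estimating epsilon from data is
#' out of scope -- and the scorecard marks it as declared, not measured.
#'
#' @param decl a [privacy_declaration()].
#' @return a [metric_result()]; smaller epsilon means stronger privacy.
#' @export
record_dp_declaration <- function(decl) {
  stopifnot(inherits(decl, "privacy_declaration"))
  metric_result("Differential Privacy Score", decl$epsilon,
                params = list(delta = decl$delta, mechanism = decl$mechanism,
                              provenance = "declared, not measured"))
}

#' Re-identification risk proxy via nearest-record distances
#'
#' The baseline is the median nearest-neighbour distance within the
#' reference set (each record to its closest other record). The raw value
#' is the fraction of synthetic samples whose nearest reference record lies
#' closer than `theta` times that baseline -- a memorization proxy in
#' `[0, 1]`; exact copies of training records always flag. Params carry the
#' minimum synthetic-to-reference distance.
#'
#' @param reference a [feature_matrix()] with `n >= 2`.
#' @param synthetic a [feature_matrix()] with equal `d`.
#' @param theta closeness multiplier on the baseline (default 0.1).
#' @return a [metric_result()]; smaller is better.
#' @export
metric_reidentification_risk <- function(reference, synthetic, theta = 0.1) {
  stopifnot(inherits(reference, "feature_matrix"),
            inherits(synthetic, "feature_matrix"))
  R <- reference$values; S <- synthetic$values
  if (ncol(R) != ncol(S)) stop_smd("dimension mismatch")
  if (nrow(R) < 2L) stop_smd("reference needs n >= 2 for a baseline")
  Drr <- cross_dist(R, R)
  diag(Drr) <- Inf
  baseline <- stats::median(apply(Drr, 1, min))
  Dsr <- cross_dist(S, R)
  nearest <- apply(Dsr, 1, min)
  raw <- mean(nearest < theta * baseline)
  metric_result("Re-identification Risk", raw,
                params = list(theta = theta, baseline = baseline,
                              min_distance = min(nearest)))
}
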