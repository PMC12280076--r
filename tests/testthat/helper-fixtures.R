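# Shared helpers for the test suite: tiny constructors and brute-force
# oracles kept deliberately independent of the implementation paths they
# check.

fm <- function(values, ...) feature_matrix(as.matrix(values), ...)

# 1-D feature matrix from a numeric vector
fm1 <- function(x) feature_matrix(matrix(x, ncol = 1))

# brute-force kNN-manifold membership: fraction of query points within the
# k-th-NN radius ball of at least one radius-set point (O(n^2), direct)
oracle_knn_fraction <- function(radius_pts, query_pts, k) {
  radii <- vapply(seq_len(nrow(radius_pts)), function(i) {
    d <- sqrt(colSums((t(radius_pts) - radius_pts[i, ])^2))
    sort(d)[k + 1]
  }, numeric(1))
  mean(vapply(seq_len(nrow(query_pts)), function(j) {
    d <- sqrt(colSums((t(radius_pts) - query_pts[j, ])^2))
    any(d <= radii)
  }, logical(1)))
}

# brute-force coverage: fraction of reference points whose own kNN ball
# contains at least one synthetic point
oracle_coverage <- function(ref, syn, k) {
  mean(vapply(seq_len(nrow(ref)), function(i) {
    dr <- sqrt(colSums((t(ref) - ref[i, ])^2))
    radius <- sort(dr)[k + 1]
    ds <- sqrt(colSums((t(syn) - ref[i, ])^2))
    any(ds <= radius)
  }, logical(1)))
}

# brute-force k-anonymity: full enumeration of quasi-identifier tuples
oracle_k_anonymity <- function(df, qi) {
  key <- apply(df[, qi, drop = FALSE], 1, paste, collapse = "|")
  min(table(key))
}

# cheap wrapped metric for consistency tests: mean of the first feature
mean_metric <- function(x) metric_result("mean-f1", mean(x$values[, 1]))

# a full-inputs evaluation exercising all seven criteria from fixtures
demo_evaluation <- function(seed = 3) {
  gen <- gen_subgrouped_embeddings(
    data.frame(label = c("grpA", "grpB"), n = c(60, 60), shift = c(0, 0.5),
               stringsAsFactors = FALSE),
    d = 3, seed = seed)
  tab <- gen_anonymity_table(40, k_star = 3, missing_rate = 0.05, seed = seed)
  rubric <- setNames(as.list(c(2, 2, 1, 2, 2, 1, 1, 2)),
                     c("generation_method", "parameters_listed",
                       "version_history", "license", "contact", "limitations",
                       "preprocessing", "intended_use"))
  config <- list(
    seed = seed,
    constraints = list(
      list(id = "note-length", target = "note_len", kind = "interval",
           lo = 0, hi = 600),
      list(id = "visits", target = "visit_count", kind = "interval",
           lo = 0, hi = 25)
    ),
    compliance = list(epsilon = 1.0, delta = 1e-5, mechanism = "DP-SGD"),
    comprehension = list(rubric = rubric, rater = "developer"),
    completeness = list(rating = 8),
    consistency = list(B = 20),
    scorecard = list(
      section_1_general = list(name = "fixture-smd", release_date = "2026-01-01"),
      section_3_task = list(task_performance = "AUC 0.91 on toy task")
    )
  )
  run_evaluation(config,
                 data = list(reference = gen$reference,
                             synthetic = gen$synthetic,
                             tabular = tab))
}
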