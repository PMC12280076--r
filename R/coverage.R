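# Diversity / representativeness metrics.

#' kNN-manifold recall and coverage
#'
#' `mode = "recall"`: fraction of reference samples inside the synthetic
#' kNN-radius manifold (radii computed within the synthetic set).
#' `mode = "coverage"`: fraction of reference samples whose own kNN ball
#' (radius from the reference set) contains at least one synthetic sample.
#' Both lie in `[0, 1]`; low values flag mode collapse.
#'
#' @param reference,synthetic [feature_matrix()] objects with equal `d`.
#' @param k neighbour count defining ball radii; the radius-defining set
#'   must have `n > k`.
#' @param mode `"recall"` or `"coverage"`.
#' @return a [metric_result()]; larger is better.
#' @export
metric_knn_support <- function(reference, synthetic, k = 3L,
                               mode = c("recall", "coverage")) {
  mode <- match.arg(mode)
  if (mode == "recall") {
    res <- knn_manifold_membership(radius_set = synthetic,
                                   query_set = reference, k = k)
    metric_result("Recall", res$fraction,
                  params = list(k = k, construction = "kNN-radius manifold"))
  } else {
    R <- reference$values; S <- synthetic$values
    if (ncol(R) != ncol(S)) stop_smd("dimension mismatch")
    k <- as.integer(k)
    if (nrow(R) <= k) stop_smd("reference needs n > k (n=%d, k=%d)", nrow(R), k)
    Drr <- cross_dist(R, R)
    radii <- apply(Drr, 1, function(row) sort(row)[k + 1L])
    Drs <- cross_dist(R, S)
    covered <- vapply(seq_len(nrow(R)), function(i) {
      any(Drs[i, ] <= radii[i])
    }, logical(1))
    metric_result("Coverage", mean(covered),
                  params = list(k = k, construction = "reference kNN balls"))
  }
}

#' Convex-hull volume ratio in a PCA-reduced plane
#'
#' Fits a PCA pipeline on the reference, projects both sets to `dims`
#' dimensions, and reports hull volume(synthetic) / hull volume(reference).
#' High-dimensional hulls are degenerate and exponentially costly, so the
#' reduced space (default a 2-D plane, where volume is area) is where the
#' spread comparison happens; `dims = 1` uses range width. Each projected
#' set must have at least `dims + 1` affinely independent points.
#'
#' @param reference,synthetic [feature_matrix()] objects with equal `d`.
#' @param dims dimension of the reduced space (1 or 2).
#' @return a [metric_result()] with both volumes in params.
#' @export
metric_hull_ratio <- function(reference, synthetic, dims = 2L) {
  stopifnot(inherits(reference, "feature_matrix"),
            inherits(synthetic, "feature_matrix"))
  dims <- as.integer(dims)
  if (dims < 1L || dims > 2L) {
    stop_smd("hull volume supports dims 1 or 2 (got %d)", dims)
  }
  d <- ncol(reference$values)
  pipe <- fit_embedding_pipeline(reference, k = min(dims, d))
  Zr <- apply_embedding(pipe, reference)$values
  Zs <- apply_embedding(pipe, synthetic)$values
  vol <- function(Z, label) {
    if (dims == 1L || ncol(Z) == 1L) {
      v <- max(Z[, 1]) - min(Z[, 1])
      if (v <= 0) stop_smd("%s set is degenerate in the reduced space", label)
      return(v)
    }
    if (nrow(Z) < 3L) stop_smd("%s set needs >= 3 points for a 2-D hull", label)
    h <- grDevices::chull(Z[, 1], Z[, 2])
    if (length(h) < 3L) stop_smd("%s set is affinely degenerate", label)
    x <- Z[h, 1]; y <- Z[h, 2]
    area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    # collinear points can survive chull with a floating-point sliver area
    bbox <- max(diff(range(Z[, 1])) * diff(range(Z[, 2])),
                .Machine$double.eps)
    if (area <= 1e-10 * bbox) stop_smd("%s set is affinely degenerate", label)
    area
  }
  v_ref <- vol(Zr, "reference")
  v_syn <- vol(Zs, "synthetic")
  metric_result("Convex Hull Volume", v_syn / v_ref,
                params = list(dims = dims, volume_reference = v_ref,
                              volume_synthetic = v_syn))
}

#' Kernel diversity (Vendi or DPP log-determinant)
#'
#' Builds the cosine-similarity kernel `K` of the L2-normalized rows (unit
#' diagonal, so eigenvalues of `K/n` sum to 1). `kind = "vendi"` is the
#' effective number of distinct samples
#' \eqn{\exp(-\sum_i \lambda_i \log \lambda_i)} over the eigenvalues of
#' `K/n` (with `0 log 0 = 0`), in `[1, n]`. `kind = "dpp_logdet"` is
#' `(1/n) log det(K + 1e-6 I)`.
#'
#' @param data a [feature_matrix()] with no zero-norm row.
#' @param kind `"vendi"` or `"dpp_logdet"`.
#' @return a [metric_result()]; larger is better.
#' @export
metric_kernel_diversity <- function(data, kind = c("vendi", "dpp_logdet")) {
  kind <- match.arg(kind)
  stopifnot(inherits(data, "feature_matrix"))
  X <- data$values
  norms <- sqrt(rowSums(X^2))
  if (any(norms == 0)) stop_smd("zero-norm row cannot be L2-normalized")
  U <- X / norms
  K <- tcrossprod(U)
  n <- nrow(K)
  if (kind == "vendi") {
    lam <- eigen(K / n, symmetric = TRUE, only.values = TRUE)$values
    lam[lam < 0] <- 0
    lam <- lam / sum(lam)
    raw <- exp(shannon_entropy(lam, base = exp(1)))
    metric_result("Vendi Score", raw,
                  params = list(kernel = "cosine", n = n))
  } else {
    raw <- determinant(K + 1e-6 * diag(n), logarithm = TRUE)$modulus[1] / n
    metric_result("Determinantal Point Processes Score", raw,
                  params = list(kernel = "cosine", ridge = 1e-6, n = n))
  }
}

#' Dispersion of the synthetic embedding
#'
#' `kind = "variance"`: trace of the synthetic sample covariance; when a
#' reference is supplied, params add the synthetic/reference trace ratio.
#' `kind = "entropy"`: mean over features of the Shannon entropy (bits) of
#' the 32-bin marginal histogram; bins span the synthetic range, or the
#' pooled range when a reference is given.
#'
#' @param synthetic a [feature_matrix()] (`n >= 2` for variance).
#' @param reference optional [feature_matrix()] supplying the comparison
#'   range / variance baseline.
#' @param kind `"variance"` or `"entropy"`.
#' @param bins histogram bin count for entropy.
#' @return a [metric_result()]; larger is better.
#' @export
metric_dispersion <- function(synthetic, reference = NULL,
                              kind = c("variance", "entropy"), bins = 32L) {
  kind <- match.arg(kind)
  stopifnot(inherits(synthetic, "feature_matrix"))
  Xs <- synthetic$values
  if (kind == "variance") {
    if (nrow(Xs) < 2L) stop_smd("variance needs n >= 2")
    raw <- sum(diag(stats::cov(Xs)))
    params <- list(kind = "trace of sample covariance")
    if (!is.null(reference)) {
      tr_ref <- sum(diag(stats::cov(reference$values)))
      params$ratio_to_reference <- raw / tr_ref
    }
    metric_result("Variance", raw, params = params)
  } else {
    ent <- vapply(seq_len(ncol(Xs)), function(j) {
      x <- Xs[, j]
      rng <- if (is.null(reference)) range(x) else range(c(x, reference$values[, j]))
      if (rng[2] == rng[1]) return(0)
      edges <- seq(rng[1], rng[2], length.out = bins + 1L)
      counts <- bin_counts(x, edges)
      shannon_entropy(counts / sum(counts), base = 2)
    }, numeric(1))
    metric_result("Entropy", mean(ent),
                  params = list(bins = bins, per_feature = ent,
                                range = if (is.null(reference)) "synthetic" else "pooled"))
  }
}

#' Cluster occupancy of the reference partition
#'
#' Fits seeded k-means (10 restarts) on the reference, assigns each
#' synthetic sample to its nearest centroid, and calls a cluster occupied
#' when its synthetic share reaches half the uniform share
#' (`0.5 / n_clusters`). The raw value is occupied clusters / `n_clusters`,
#' in `[0, 1]`; 1 means the synthetic data reaches every reference mode.
#'
#' @param reference a [feature_matrix()] with `n >= n_clusters`.
#' @param synthetic a non-empty [feature_matrix()] with equal `d`.
#' @param n_clusters number of k-means clusters.
#' @param seed integer seed for the k-means restarts.
#' @return a [metric_result()]; larger is better.
#' @export
metric_cluster_occupancy <- function(reference, synthetic, n_clusters = 8L,
                                     seed = 1L) {
  stopifnot(inherits(reference, "feature_matrix"),
            inherits(synthetic, "feature_matrix"))
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L) stop_smd("n_clusters must be >= 1")
  R <- reference$values; S <- synthetic$values
  if (ncol(R) != ncol(S)) stop_smd("dimension mismatch")
  if (nrow(R) < n_clusters) stop_smd("reference smaller than n_clusters")
  if (nrow(S) < 1L) stop_smd("synthetic set is empty")
  km <- with_seed(seed, stats::kmeans(R, centers = n_clusters, nstart = 10L,
                                      iter.max = 50L))
  assign_idx <- apply(cross_dist(S, km$centers), 1, which.min)
  shares <- tabulate(assign_idx, nbins = n_clusters) / nrow(S)
  threshold <- 0.5 / n_clusters
  occupied <- sum(shares >= threshold)
  metric_result("Clustering-Based Metrics", occupied / n_clusters,
                params = list(n_clusters = n_clusters, seed = seed,
                              occupancy_threshold = threshold,
                              shares = shares, restarts = 10L))
}

#' Inception-style score from user-supplied class probabilities
#'
#' \eqn{\exp(\mathbb{E}_i\, KL(p(y|x_i)\,\|\,\bar p(y)))} (natural log) over
#' a user-supplied n x C class-probability matrix -- any classifier can
#' produce it, decoupling the score from a specific network. The value lies
#' in `[1, C]`.
#'
#' @param class_probabilities numeric matrix, rows summing to 1 within 1e-6.
#' @return a [metric_result()]; larger is better.
#' @export
metric_inception_style_score <- function(class_probabilities) {
  P <- as.matrix(class_probabilities)
  if (ncol(P) < 2L) stop_smd("need at least 2 classes")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-6)) {
    stop_smd("rows must be probability vectors (non-negative, sum 1)")
  }
  marginal <- colMeans(P)
  kl <- apply(P, 1, function(p) {
    nz <- p > 0
    sum(p[nz] * log(p[nz] / marginal[nz]))
  })
  metric_result("Inception Score", exp(mean(kl)),
                params = list(n_classes = ncol(P), n = nrow(P)))
}
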