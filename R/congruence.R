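# Alignment metrics between synthetic and reference distributions.

#' Fréchet distance between Gaussian fits of two embeddings
#'
#' The classic two-moment distance
#' \deqn{\|\mu_r-\mu_s\|^2 + \mathrm{tr}(\Sigma_r+\Sigma_s-2(\Sigma_r\Sigma_s)^{1/2})}
#' computed from sample means and covariances (denominator n-1). The trace
#' of the matrix square root is taken as the sum of square roots of the
#' eigenvalues of \eqn{\Sigma_r\Sigma_s}; tiny negative eigenvalues (above
#' -1e-8 relative) are clamped to zero, anything more negative errors. The
#' computation is embedding-generic: it applies to whatever feature space is
#' supplied, with no pretrained network involved.
#'
#' @param reference,synthetic [feature_matrix()] objects with equal `d` and
#'   `n >= 2` each.
#' @return a [metric_result()]; smaller is better, 0 means identical moments.
#' @export
metric_fid <- function(reference, synthetic) {
  stopifnot(inherits(reference, "feature_matrix"),
            inherits(synthetic, "feature_matrix"))
  Xr <- reference$values; Xs <- synthetic$values
  if (ncol(Xr) != ncol(Xs)) stop_smd("dimension mismatch")
  if (nrow(Xr) < 2L || nrow(Xs) < 2L) stop_smd("FID needs n >= 2 on both sides")
  mu_r <- colMeans(Xr); mu_s <- colMeans(Xs)
  S_r <- stats::cov(Xr); S_s <- stats::cov(Xs)
  ev <- eigen(S_r %*% S_s, only.values = TRUE)$values
  ev <- Re(ev)
  scale_ref <- max(abs(ev), 1)
  if (any(ev < -1e-8 * scale_ref)) {
    stop_smd("covariance product has a negative eigenvalue beyond tolerance")
  }
  ev[ev < 0] <- 0
  raw <- sum((mu_r - mu_s)^2) + sum(diag(S_r)) + sum(diag(S_s)) -
    2 * sum(sqrt(ev))
  raw <- max(raw, 0)
  metric_result("Fréchet Inception Distance", raw,
                params = list(n_reference = nrow(Xr), n_synthetic = nrow(Xs),
                              covariance = "sample (n-1)"))
}

#' Mean per-feature marginal divergence
#'
#' Per feature, compares the reference and synthetic marginal
#' distributions:
#' `kind = "jsd"` bins both samples on shared edges spanning the pooled
#' min-max (default 32 bins) and takes the Jensen-Shannon divergence in
#' base-2 logs, so each feature's value lies in `[0, 1]`; `kind = "emd"`
#' takes the exact 1-D Wasserstein-1 distance between the empirical
#' marginals (sorted samples, no binning). The raw value is the mean over
#' features. A feature whose pooled range has zero width contributes 0 under
#' `jsd` and is flagged in params.
#'
#' @param reference,synthetic [feature_matrix()] objects with equal `d`.
#' @param kind `"jsd"` or `"emd"`.
#' @param bins bin count for `jsd`.
#' @return a [metric_result()]; smaller is better.
#' @export
metric_marginal_divergence <- function(reference, synthetic,
                                       kind = c("jsd", "emd"), bins = 32L) {
  kind <- match.arg(kind)
  stopifnot(inherits(reference, "feature_matrix"),
            inherits(synthetic, "feature_matrix"))
  Xr <- reference$values; Xs <- synthetic$values
  if (ncol(Xr) != ncol(Xs)) stop_smd("dimension mismatch")
  d <- ncol(Xr)
  degenerate <- character()
  vals <- vapply(seq_len(d), function(j) {
    xr <- Xr[, j]; xs <- Xs[, j]
    if (kind == "emd") return(wasserstein1d(xr, xs))
    lo <- min(xr, xs); hi <- max(xr, xs)
    if (hi == lo) {
      degenerate <<- c(degenerate, colnames(Xr)[j] %||% paste0("f", j))
      return(0)
    }
    edges <- seq(lo, hi, length.out = bins + 1L)
    p <- bin_counts(xr, edges); p <- p / sum(p)
    q <- bin_counts(xs, edges); q <- q / sum(q)
    m <- (p + q) / 2
    kl <- function(a, b) {
      nz <- a > 0
      sum(a[nz] * log2(a[nz] / b[nz]))
    }
    (kl(p, m) + kl(q, m)) / 2
  }, numeric(1))
  params <- list(kind = kind, n_features = d)
  if (kind == "jsd") {
    params$bins <- bins
    params$binning <- "shared edges over pooled min-max"
    if (length(degenerate)) params$zero_width_features <- degenerate
  }
  name <- if (kind == "jsd") "Jensen-Shannon Divergence" else "Earth Mover's Distance"
  metric_result(name, mean(vals), params = c(params, list(per_feature = vals)))
}

#' Centroid alignment between two embeddings
#'
#' `kind = "cosine"` is the cosine of the angle between the reference and
#' synthetic centroid vectors (both must be nonzero), in `[-1, 1]`.
#' `kind = "distance"` is the mean Euclidean distance from synthetic samples
#' to the reference centroid; params carry the reference's own mean
#' distance-to-centroid as a baseline for interpreting the raw value.
#'
#' @param reference,synthetic [feature_matrix()] objects with equal `d`.
#' @param kind `"cosine"` or `"distance"`.
#' @return a [metric_result()].
#' @export
metric_centroid_alignment <- function(reference, synthetic,
                                      kind = c("cosine", "distance")) {
  kind <- match.arg(kind)
  stopifnot(inherits(reference, "feature_matrix"),
            inherits(synthetic, "feature_matrix"))
  Xr <- reference$values; Xs <- synthetic$values
  if (ncol(Xr) != ncol(Xs)) stop_smd("dimension mismatch")
  c_r <- colMeans(Xr); c_s <- colMeans(Xs)
  if (kind == "cosine") {
    nr <- sqrt(sum(c_r^2)); ns <- sqrt(sum(c_s^2))
    if (nr == 0 || ns == 0) stop_smd("cosine alignment undefined for a zero centroid")
    raw <- sum(c_r * c_s) / (nr * ns)
    raw <- max(-1, min(1, raw))
    metric_result("Cosine Similarity", raw,
                  params = list(construction = "centroid cosine (not mean pairwise)"))
  } else {
    dists <- sqrt(rowSums(sweep(Xs, 2, c_r)^2))
    baseline <- mean(sqrt(rowSums(sweep(Xr, 2, c_r)^2)))
    metric_result("Distance to Centroid", mean(dists),
                  params = list(reference_baseline = baseline))
  }
}

#' Paired image similarity (PSNR or SSIM)
#'
#' Pairs image i of the reference with image i of the synthetic set.
#' `kind = "psnr"` computes per pair \eqn{10\log_{10}(L^2/\mathrm{MSE})},
#' capped at 100 dB when MSE = 0. `kind = "ssim"` computes the mean local
#' structural-similarity index with an 11x11 Gaussian window (sigma 1.5) and
#' the standard constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. The raw
#' value is the mean over pairs; per-pair values are kept in params.
#'
#' @param reference,synthetic [image_set()] objects with equal counts,
#'   pairwise equal shapes and a shared dynamic range.
#' @param kind `"psnr"` or `"ssim"`.
#' @return a [metric_result()]; larger is better.
#' @export
metric_paired_image_similarity <- function(reference, synthetic,
                                           kind = c("psnr", "ssim")) {
  kind <- match.arg(kind)
  stopifnot(inherits(reference, "image_set"), inherits(synthetic, "image_set"))
  if (length(reference$images) != length(synthetic$images)) {
    stop_smd("paired similarity needs equal image counts")
  }
  if (reference$dynamic_range != synthetic$dynamic_range) {
    stop_smd("image sets must share a dynamic range")
  }
  L <- reference$dynamic_range
  per_pair <- vapply(seq_along(reference$images), function(i) {
    a <- reference$images[[i]]; b <- synthetic$images[[i]]
    if (!all(dim(a) == dim(b))) stop_smd("shape mismatch in pair %d", i)
    if (kind == "psnr") {
      mse <- mean((a - b)^2)
      if (mse == 0) 100 else min(10 * log10(L^2 / mse), 100)
    } else {
      ssim_pair(a, b, L)
    }
  }, numeric(1))
  name <- if (kind == "psnr") "Peak Signal-to-Noise Ratio" else "Structural Similarity Index"
  params <- list(per_pair = per_pair, n_pairs = length(per_pair))
  if (kind == "psnr") {
    params$cap_db <- 100
  } else {
    params <- c(params, list(window = 11L, sigma = 1.5,
                             C1 = (0.01 * L)^2, C2 = (0.03 * L)^2))
  }
  metric_result(name, mean(per_pair), params = params)
}

# Mean local SSIM with Gaussian weighting, "valid" convolution (no padding),
# matching the standard parameterization.
ssim_pair <- function(a, b, L, window = 11L, sigma = 1.5) {
  if (any(dim(a) < window)) {
    # image smaller than the window: single global window, uniform weights
    w <- matrix(1 / length(a), nrow(a), ncol(a))
    return(ssim_stat(sum(w * a), sum(w * b), sum(w * a^2), sum(w * b^2),
                     sum(w * a * b), L))
  }
  g <- stats::dnorm(seq_len(window) - (window + 1) / 2, sd = sigma)
  g <- g / sum(g)
  conv <- function(img) {
    # separable Gaussian filtering, valid region only
    tmp <- apply(img, 2, function(col) stats::filter(col, g, sides = 2))
    out <- t(apply(tmp, 1, function(row) stats::filter(row, g, sides = 2)))
    half <- (window - 1L) / 2L
    out[(half + 1):(nrow(img) - half), (half + 1):(ncol(img) - half), drop = FALSE]
  }
  mu_a <- conv(a); mu_b <- conv(b)
  s_aa <- conv(a * a) - mu_a^2
  s_bb <- conv(b * b) - mu_b^2
  s_ab <- conv(a * b) - mu_a * mu_b
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2)
  mean(num / den)
}

ssim_stat <- function(ma, mb, maa, mbb, mab, L) {
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  saa <- maa - ma^2; sbb <- mbb - mb^2; sab <- mab - ma * mb
  ((2 * ma * mb + C1) * (2 * sab + C2)) /
    ((ma^2 + mb^2 + C1) * (saa + sbb + C2))
}

#' kNN-manifold precision
#'
#' Builds a ball of radius "distance to the k-th nearest reference
#' neighbour" around each reference point; the metric is the fraction of
#' synthetic samples lying inside at least one such ball, in `[0, 1]`. High
#' precision means synthetic samples stay on the reference manifold.
#'
#' @param reference a [feature_matrix()] with `n > k`.
#' @param synthetic a [feature_matrix()] with equal `d`.
#' @param k neighbour count defining the ball radii.
#' @return a [metric_result()]; larger is better.
#' @export
metric_knn_precision <- function(reference, synthetic, k = 3L) {
  res <- knn_manifold_membership(radius_set = reference,
                                 query_set = synthetic, k = k)
  metric_result("Precision", res$fraction,
                params = list(k = k, construction = "kNN-radius manifold"))
}

# Shared helper: fraction of query points within the union of kNN-radius
# balls around the radius-defining set.
knn_manifold_membership <- function(radius_set, query_set, k) {
  stopifnot(inherits(radius_set, "feature_matrix"),
            inherits(query_set, "feature_matrix"))
  R <- radius_set$values; Q <- query_set$values
  if (ncol(R) != ncol(Q)) stop_smd("dimension mismatch")
  k <- as.integer(k)
  if (nrow(R) <= k) stop_smd("radius-defining set needs n > k (n=%d, k=%d)",
                             nrow(R), k)
  Drr <- cross_dist(R, R)
  radii <- apply(Drr, 1, function(row) sort(row)[k + 1L])  # excl. self (d=0)
  Dqr <- cross_dist(Q, R)
  inside <- vapply(seq_len(nrow(Q)), function(i) {
    any(Dqr[i, ] <= radii)
  }, logical(1))
  list(fraction = mean(inside), inside = inside, radii = radii)
}
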