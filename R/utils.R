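#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit integer derived from (seed, stream name).  Each
# generator draws from its own stream so adding a generator never perturbs
# the values another one produces under the same user seed.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h * 2654435) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Exact 1-D Wasserstein-1 distance between two empirical samples, computed
# as the integral of |F1 - F2| over the merged support (no binning).
wasserstein1d <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  all_v <- sort(unique(c(x, y)))
  if (length(all_v) == 1L) return(0)
  Fx <- stats::ecdf(x)(all_v)
  Fy <- stats::ecdf(y)(all_v)
  gaps <- diff(all_v)
  sum(abs(Fx - Fy)[-length(all_v)] * gaps)
}

# Shannon entropy of a probability vector; `base` 2 gives bits.
shannon_entropy <- function(p, base = 2) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log(p)) / log(base)
}

# Histogram counts over fixed edges; values exactly at the upper edge fall in
# the last bin (right-closed final bin, as hist(include.lowest=TRUE) does).
bin_counts <- function(x, edges) {
  n_bins <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = n_bins)
}

# Pairwise Euclidean distances between rows of a and rows of b (n_a x n_b).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_smd <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
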