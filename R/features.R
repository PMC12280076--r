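#' Fit an embedding pipeline on reference data
#'
#' Standardization (per-feature center/scale from the reference) optionally
#' followed by a top-`k` principal-component projection of the standardized
#' reference. The pipeline is fitted on the reference only and then applied
#' identically to both datasets, so the synthetic data never influences the
#' space it is judged in. Zero-variance features get scale 1 (their
#' standardized values are exactly 0). The sign of each principal direction
#' is fixed by making its largest-magnitude loading positive, so outputs are
#' bit-stable across runs.
#'
#' @param reference a [feature_matrix()] with `n >= 2`.
#' @param k optional number of principal components, `k <= d`.
#' @return an object of class `embedding_pipeline`.
#' @export
fit_embedding_pipeline <- function(reference, k = NULL) {
  stopifnot(inherits(reference, "feature_matrix"))
  X <- reference$values
  if (nrow(X) < 2L) stop_smd("pipeline fitting needs n >= 2 reference samples")
  d <- ncol(X)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L || k > d) stop_smd("k must satisfy 1 <= k <= d (d = %d)", d)
  }
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  projection <- NULL
  if (!is.null(k)) {
    S <- stats::cov(Z)
    eig <- eigen(S, symmetric = TRUE)
    V <- eig$vectors[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      i_max <- which.max(abs(V[, j]))
      if (V[i_max, j] < 0) V[, j] <- -V[, j]
    }
    projection <- V
  }
  structure(
    list(per_feature_center = center, per_feature_scale = scale,
         projection = projection, d = d, k = k %||% d,
         fitted_on = sprintf("reference[n=%d,d=%d]", nrow(X), d)),
    class = "embedding_pipeline"
  )
}

#' Apply an embedding pipeline to a dataset
#'
#' Standardizes with the pipeline's reference-derived center/scale, then
#' projects when the pipeline carries a principal basis. Sample ids and
#' subgroup labels are carried through.
#'
#' @param pipeline an [fit_embedding_pipeline()] result.
#' @param data a [feature_matrix()] with the dimension the pipeline was
#'   fitted on.
#' @return a [feature_matrix()] in the embedded space.
#' @export
apply_embedding <- function(pipeline, data) {
  stopifnot(inherits(pipeline, "embedding_pipeline"),
            inherits(data, "feature_matrix"))
  X <- data$values
  if (ncol(X) != pipeline$d) {
    stop_smd("dimension mismatch: data d=%d, pipeline fitted on d=%d",
             ncol(X), pipeline$d)
  }
  Z <- sweep(sweep(X, 2, pipeline$per_feature_center), 2,
             pipeline$per_feature_scale, "/")
  if (!is.null(pipeline$projection)) Z <- Z %*% pipeline$projection
  feature_matrix(Z, sample_ids = data$sample_ids, subgroups = data$subgroups,
                 feature_names = if (is.null(pipeline$projection))
                   data$feature_names else paste0("pc", seq_len(ncol(Z))))
}

#' Extract a fixed 8-feature descriptor per image
#'
#' A deterministic, training-free image descriptor whose entries are, in
#' order: mean intensity, intensity standard deviation, 5th percentile,
#' 95th percentile, Shannon entropy (bits) of the 32-bin intensity histogram
#' over `[0, L]`, mean absolute horizontal gradient, mean absolute vertical
#' gradient, and foreground fraction (pixels above the image's Otsu
#' threshold). Quantiles use the type-7 convention.
#'
#' @param images an [image_set()].
#' @return a [feature_matrix()] with one row per image.
#' @export
extract_image_features <- function(images) {
  stopifnot(inherits(images, "image_set"))
  L <- images$dynamic_range
  feats <- t(vapply(images$images, function(img) {
    v <- as.vector(img)
    p <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
    counts <- bin_counts(v, seq(0, L, length.out = 33L))
    ent <- shannon_entropy(counts / sum(counts), base = 2)
    # horizontal gradient: differences along rows (across columns)
    gh <- if (ncol(img) > 1L) mean(abs(img[, -1, drop = FALSE] -
                                       img[, -ncol(img), drop = FALSE])) else 0
    gv <- if (nrow(img) > 1L) mean(abs(img[-1, , drop = FALSE] -
                                       img[-nrow(img), , drop = FALSE])) else 0
    fg <- mean(v > otsu_threshold(v, L))
    c(mean(v), stats::sd(v) * sqrt((length(v) - 1) / length(v)), p[1], p[2],
      ent, gh, gv, fg)
  }, numeric(8)))
  feature_matrix(feats, sample_ids = images$ids,
                 feature_names = c("mean", "sd", "p05", "p95", "hist_entropy",
                                   "grad_h", "grad_v", "fg_fraction"))
}

# Otsu threshold over a 256-level quantization of [0, L]; returns the
# intensity maximizing between-class variance. Constant images return L
# (no foreground).
otsu_threshold <- function(v, L) {
  if (length(unique(v)) == 1L) return(L)
  edges <- seq(0, L, length.out = 257L)
  counts <- bin_counts(v, edges)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, length(p))
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  edges[which.max(bcv) + 1L]
}

#' Extract bag-of-token count features from documents
#'
#' Tokenizes on whitespace and punctuation, lowercases, counts tokens over
#' the vocabulary (built from the corpus when not supplied, sorted
#' lexicographically) and L2-normalizes each row. Documents with no
#' in-vocabulary tokens stay all-zero.
#'
#' @param documents non-empty character vector.
#' @param vocabulary optional character vector of tokens.
#' @return a [feature_matrix()], one row per document, one feature per token.
#' @export
extract_text_features <- function(documents, vocabulary = NULL) {
  if (length(documents) == 0L) stop_smd("document list is empty")
  token_lists <- lapply(documents, function(doc) {
    toks <- strsplit(tolower(doc), "[[:space:][:punct:]]+")[[1]]
    toks[nzchar(toks)]
  })
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(token_lists)))
  }
  if (length(vocabulary) == 0L) stop_smd("vocabulary is empty after tokenization")
  counts <- t(vapply(token_lists, function(toks) {
    tab <- table(factor(toks, levels = vocabulary))
    as.numeric(tab)
  }, numeric(length(vocabulary))))
  norms <- sqrt(rowSums(counts^2))
  norms[norms == 0] <- 1
  feature_matrix(counts / norms, feature_names = vocabulary)
}

#' Select a subset of samples for local assessment
#'
#' Local quality assessment (e.g. lesion regions only) is a metric run on a
#' selected subset: `select_local` subsets a feature matrix or image set by
#' sample ids or a boolean mask, preserving original order.
#'
#' @param data a [feature_matrix()] or [image_set()].
#' @param selector character vector of ids, or logical mask of length n.
#' @return the same type as `data`, restricted to the selection.
#' @export
select_local <- function(data, selector) {
  n <- if (inherits(data, "feature_matrix")) nrow(data$values)
       else if (inherits(data, "image_set")) length(data$images)
       else stop_smd("select_local expects a feature_matrix or image_set")
  ids <- if (inherits(data, "feature_matrix")) data$sample_ids else data$ids
  if (is.logical(selector)) {
    if (length(selector) != n) stop_smd("mask length %d != n = %d",
                                        length(selector), n)
    idx <- which(selector)
  } else {
    if (is.null(ids)) stop_smd("id selection requires sample ids")
    unknown <- setdiff(selector, ids)
    if (length(unknown)) stop_smd("unknown ids: %s", paste(unknown, collapse = ", "))
    idx <- which(ids %in% selector)
  }
  if (length(idx) == 0L) stop_smd("empty selection: metrics need n >= 1")
  if (inherits(data, "feature_matrix")) {
    feature_matrix(data$values[idx, , drop = FALSE],
                   sample_ids = if (!is.null(ids)) ids[idx] else NULL,
                   subgroups = if (!is.null(data$subgroups)) data$subgroups[idx] else NULL,
                   feature_names = data$feature_names)
  } else {
    image_set(data$images[idx], dynamic_range = data$dynamic_range,
              ids = if (!is.null(ids)) ids[idx] else NULL)
  }
}
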