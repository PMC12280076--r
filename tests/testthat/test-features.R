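test_that("rank-1 data projected to 1-D preserves pairwise distances", {
  t_vals <- seq(-2, 2, length.out = 9)
  X <- fm(cbind(3 * t_vals, 4 * t_vals))  # points on a line
  pipe <- fit_embedding_pipeline(X, k = 1)
  Z <- apply_embedding(pipe, X)$values
  d_in <- as.matrix(dist(scale(X$values)))
  d_out <- as.matrix(dist(Z))
  expect_lt(max(abs(d_in - d_out)), 1e-8)
})

test_that("constant feature columns standardize to zero with scale 1", {
  X <- fm(cbind(rnorm(10), rep(7, 10)))
  pipe <- fit_embedding_pipeline(X)
  expect_equal(pipe$per_feature_scale[2], 1)
  Z <- apply_embedding(pipe, X)$values
  expect_true(all(Z[, 2] == 0))
})

test_that("full-rank PCA reconstructs the standardized input", {
  set.seed(11)
  X <- fm(matrix(rnorm(50), 10, 5))
  pipe <- fit_embedding_pipeline(X, k = 5)
  Z <- apply_embedding(pipe, X)$values
  recon <- Z %*% t(pipe$projection)
  std <- scale(X$values)
  attr(std, "scaled:center") <- attr(std, "scaled:scale") <- NULL
  expect_lt(max(abs(recon - std)), 1e-8)
  # orthonormal basis
  expect_lt(max(abs(crossprod(pipe$projection) - diag(5))), 1e-8)
})

test_that("applying the pipeline to its own reference centers the columns", {
  set.seed(12)
  X <- fm(matrix(rnorm(60), 12, 5))
  pipe <- fit_embedding_pipeline(X)
  Z <- apply_embedding(pipe, X)$values
  expect_lt(max(abs(colMeans(Z))), 1e-8)
  # single sample passes through with the right shape
  one <- apply_embedding(pipe, fm(X$values[1, , drop = FALSE]))
  expect_equal(dim(one$values), c(1L, 5L))
  expect_error(apply_embedding(pipe, fm(matrix(0, 2, 3))), "mismatch")
})

test_that("pipeline application commutes with row subsetting", {
  set.seed(13)
  X <- fm(matrix(rnorm(80), 16, 5), sample_ids = paste0("s", 1:16))
  pipe <- fit_embedding_pipeline(X, k = 3)
  mask <- rep(c(TRUE, FALSE), 8)
  a <- apply_embedding(pipe, select_local(X, mask))$values
  b <- select_local(apply_embedding(pipe, X), mask)$values
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("pipeline fitting rejects invalid k and tiny references", {
  X <- fm(matrix(rnorm(10), 5, 2))
  expect_error(fit_embedding_pipeline(X, k = 3), "k must satisfy")
  expect_error(fit_embedding_pipeline(fm(matrix(1, 1, 2))), "n >= 2")
})

test_that("image descriptor matches hand computation on a 4-pixel image", {
  # column-major: [[0,255],[0,255]] has rows (0,255) / (0,255)
  img <- matrix(c(0, 0, 255, 255), 2, 2)
  feats <- extract_image_features(image_set(list(img), 255))$values[1, ]
  expect_equal(unname(feats["mean"]), 127.5)
  expect_equal(unname(feats["sd"]), 127.5)           # population convention
  expect_equal(unname(feats["p05"]), 0)              # type-7 quantile
  expect_equal(unname(feats["p95"]), 255)
  expect_equal(unname(feats["hist_entropy"]), 1)     # two occupied bins
  expect_equal(unname(feats["grad_h"]), 255)         # across columns
  expect_equal(unname(feats["grad_v"]), 0)
  expect_equal(unname(feats["fg_fraction"]), 0.5)
})

test_that("constant images have zero spread, entropy and gradients", {
  img <- matrix(100, 8, 8)
  feats <- extract_image_features(image_set(list(img), 255))$values[1, ]
  expect_equal(unname(feats[c("sd", "hist_entropy", "grad_h", "grad_v")]),
               c(0, 0, 0, 0))
})

test_that("transposing an image swaps the two gradient features only", {
  set.seed(14)
  img <- matrix(runif(12 * 9, 0, 255), 12, 9)
  f1 <- extract_image_features(image_set(list(img), 255))$values[1, ]
  f2 <- extract_image_features(image_set(list(t(img)), 255))$values[1, ]
  expect_equal(unname(f1["grad_h"]), unname(f2["grad_v"]))
  expect_equal(unname(f1["grad_v"]), unname(f2["grad_h"]))
  others <- setdiff(names(f1), c("grad_h", "grad_v"))
  expect_equal(f1[others], f2[others])
})

test_that("image descriptor survives a PNG write/read round trip", {
  set.seed(15)
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  iset <- image_set(list(img), 255, ids = "a")
  dir <- withr::local_tempdir()
  write_image_set(iset, dir)
  back <- read_image_set(dir)
  f1 <- extract_image_features(iset)$values
  f2 <- extract_image_features(back)$values
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("text features count tokens over a lexicographic vocabulary", {
  out <- extract_text_features(c("a b a"), vocabulary = c("a", "b"))
  expect_equal(out$values[1, ], c(a = 2, b = 1) / sqrt(5))

  dup <- extract_text_features(c("chest pain, acute", "chest pain acute!"))
  expect_equal(dup$values[1, ], dup$values[2, ])
  expect_equal(sum(dup$values[1, ] * dup$values[2, ]), 1)  # cosine 1

  disj <- extract_text_features(c("alpha beta", "gamma delta"))
  expect_equal(sum(disj$values[1, ] * disj$values[2, ]), 0)
})

test_that("select_local subsets by id and rejects bad selectors", {
  X <- fm(matrix(1:6, 3, 2), sample_ids = c("s1", "s2", "s3"))
  all_sel <- select_local(X, c("s1", "s2", "s3"))
  expect_equal(all_sel$values, X$values)
  one <- select_local(X, "s2")
  expect_equal(one$sample_ids, "s2")
  expect_equal(nrow(one$values), 1L)
  expect_error(select_local(X, "s9"), "unknown ids")
  expect_error(select_local(X, logical(0)), "mask length")
  expect_error(select_local(X, c(FALSE, FALSE, FALSE)), "empty selection")
})
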