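test_that("FID is zero for identical inputs and matches the 1-D closed form", {
  set.seed(21)
  X <- fm(matrix(rnorm(100), 25, 4))
  expect_lt(metric_fid(X, X)$raw_value, 1e-8)

  # 1-D closed form (mu_r - mu_s)^2 + (sd_r - sd_s)^2 over 20 random draws
  for (i in 1:20) {
    xr <- rnorm(40, mean = runif(1, -3, 3), sd = runif(1, 0.3, 3))
    xs <- rnorm(40, mean = runif(1, -3, 3), sd = runif(1, 0.3, 3))
    got <- metric_fid(fm1(xr), fm1(xs))$raw_value
    want <- (mean(xr) - mean(xs))^2 + (sd(xr) - sd(xs))^2
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("FID reproduces hand-constructed moment differences", {
  # sample moments mu_r=0, mu_s=2, sd_r=sd_s=1  ->  4
  base <- c(-1, 0, 1) / sd(c(-1, 0, 1))
  expect_equal(metric_fid(fm1(base), fm1(base + 2))$raw_value, 4,
               tolerance = 1e-9)
  # equal means, sd_r=1, sd_s=3  ->  (1-3)^2 = 4
  expect_equal(metric_fid(fm1(base), fm1(3 * base))$raw_value, 4,
               tolerance = 1e-9)
  expect_error(metric_fid(fm1(1), fm1(c(1, 2))), "n >= 2")
})

test_that("JSD hits its 0 and 1 endpoints and EMD recovers location shifts", {
  set.seed(22)
  X <- fm(matrix(rnorm(60), 30, 2))
  expect_equal(metric_marginal_divergence(X, X, "jsd")$raw_value, 0)

  lo <- fm1(runif(50, 0, 1))
  hi <- fm1(runif(50, 10, 11))      # disjoint supports
  expect_equal(metric_marginal_divergence(lo, hi, "jsd")$raw_value, 1,
               tolerance = 1e-12)

  x <- rnorm(80)
  expect_equal(metric_marginal_divergence(fm1(x), fm1(x + 2.5), "emd")$raw_value,
               2.5, tolerance = 1e-9)
})

test_that("EMD is symmetric and satisfies the triangle inequality", {
  set.seed(23)
  for (trial in 1:10) {
    a <- rnorm(15); b <- rnorm(12, 1); c <- runif(18, -2, 2)
    dab <- metric_marginal_divergence(fm1(a), fm1(b), "emd")$raw_value
    dba <- metric_marginal_divergence(fm1(b), fm1(a), "emd")$raw_value
    dac <- metric_marginal_divergence(fm1(a), fm1(c), "emd")$raw_value
    dcb <- metric_marginal_divergence(fm1(c), fm1(b), "emd")$raw_value
    expect_equal(dab, dba, tolerance = 1e-10)
    expect_lte(dab, dac + dcb + 1e-10)
  }
})

test_that("zero-width features contribute zero JSD and are flagged", {
  X <- fm(cbind(rnorm(20), rep(5, 20)))
  Y <- fm(cbind(rnorm(20), rep(5, 20)))
  res <- metric_marginal_divergence(X, Y, "jsd")
  expect_equal(res$params$per_feature[2], 0)
  expect_length(res$params$zero_width_features, 1L)
})

test_that("centroid alignment matches hand geometry", {
  A <- fm(rbind(c(2, 0), c(0, 0)))          # centroid (1, 0)
  B <- fm(rbind(c(0, 2), c(0, 0)))          # centroid (0, 1)
  expect_equal(metric_centroid_alignment(A, B, "cosine")$raw_value, 0)
  expect_equal(metric_centroid_alignment(A, A, "cosine")$raw_value, 1)

  ref <- fm(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))  # centroid (0,0)
  syn <- fm(rbind(c(3, 4)))
  res <- metric_centroid_alignment(ref, syn, "distance")
  expect_equal(res$raw_value, 5)
  expect_equal(res$params$reference_baseline, 1)
  expect_error(metric_centroid_alignment(ref, syn, "cosine"), "zero centroid")
})

test_that("PSNR honours the identity cap and the 0 dB worst case", {
  a <- matrix(runif(64, 0, 255), 8, 8)
  ia <- image_set(list(a), 255)
  expect_equal(metric_paired_image_similarity(ia, ia, "psnr")$raw_value, 100)
  expect_equal(metric_paired_image_similarity(ia, ia, "ssim")$raw_value, 1,
               tolerance = 1e-12)
  zero <- image_set(list(matrix(0, 8, 8)), 255)
  full <- image_set(list(matrix(255, 8, 8)), 255)
  expect_equal(metric_paired_image_similarity(zero, full, "psnr")$raw_value, 0)
})

test_that("SSIM agrees with the scikit-image reference value", {
  a <- outer(0:31, 0:31, function(i, j) (7 * i + 13 * j) %% 256)
  b <- outer(0:31, 0:31, function(i, j) (5 * i + 11 * j) %% 256)
  res <- metric_paired_image_similarity(image_set(list(a), 255),
                                        image_set(list(b), 255), "ssim")
  expect_equal(res$raw_value, 0.2281175, tolerance = 1e-5)
  psnr <- metric_paired_image_similarity(image_set(list(a), 255),
                                         image_set(list(b), 255), "psnr")
  expect_equal(psnr$raw_value, 7.889232, tolerance = 1e-5)
})

test_that("paired image metrics reject mismatched sets", {
  a <- image_set(list(matrix(0, 4, 4)), 255)
  b <- image_set(list(matrix(0, 4, 4), matrix(0, 4, 4)), 255)
  expect_error(metric_paired_image_similarity(a, b, "psnr"), "equal image counts")
  c_ <- image_set(list(matrix(0, 5, 4)), 255)
  expect_error(metric_paired_image_similarity(a, c_, "psnr"), "shape mismatch")
})

test_that("kNN precision matches brute-force membership on a built grid", {
  # 5 reference points on a line, unit spacing; k=1 radius = 1
  ref <- fm(cbind(0:4, rep(0, 5)))
  syn <- fm(rbind(c(0.5, 0), c(100, 100)))
  res <- metric_knn_precision(ref, syn, k = 1)
  expect_equal(res$raw_value, 0.5)
  expect_equal(res$raw_value,
               oracle_knn_fraction(ref$values, syn$values, k = 1))
  expect_equal(metric_knn_precision(ref, ref, k = 1)$raw_value, 1)
  far <- fm(ref$values + 1000)
  expect_equal(metric_knn_precision(ref, far, k = 1)$raw_value, 0)
  expect_error(metric_knn_precision(fm(cbind(0:2, 0:2)), syn, k = 3), "n > k")
})

test_that("FID, EMD and (1 - precision) respond monotonically to mean shift", {
  deltas <- c(0, 0.5, 1, 2)
  fid_v <- emd_v <- prec_v <- numeric(length(deltas))
  for (i in seq_along(deltas)) {
    pair <- gen_embedding_pair(500, 4, shift = deltas[i], seed = 99)
    fid_v[i] <- metric_fid(pair$reference, pair$synthetic)$raw_value
    emd_v[i] <- metric_marginal_divergence(pair$reference, pair$synthetic,
                                           "emd")$raw_value
    prec_v[i] <- 1 - metric_knn_precision(pair$reference, pair$synthetic)$raw_value
  }
  expect_true(all(diff(fid_v) >= 0))
  expect_true(all(diff(emd_v) >= 0))
  expect_true(all(diff(prec_v) >= 0))
})

test_that("bounded congruence metrics respect their bounds on random pairs", {
  set.seed(24)
  for (trial in 1:50) {
    n <- sample(5:20, 1); d <- sample(1:4, 1)
    A <- fm(matrix(rnorm(n * d, sd = runif(1, 0.5, 3)), n, d))
    B <- fm(matrix(rnorm(n * d, mean = runif(1, -2, 2)), n, d))
    jsd <- metric_marginal_divergence(A, B, "jsd")$raw_value
    expect_gte(jsd, 0); expect_lte(jsd, 1)
    expect_gte(metric_fid(A, B)$raw_value, 0)
    p <- metric_knn_precision(A, B, k = min(3, n - 1))$raw_value
    expect_gte(p, 0); expect_lte(p, 1)
  }
})
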