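test_that("recall and coverage are 1 for identical sets and 0 under collapse", {
  set.seed(31)
  X <- fm(matrix(rnorm(40), 20, 2))
  expect_equal(metric_knn_support(X, X, mode = "recall")$raw_value, 1)
  expect_equal(metric_knn_support(X, X, mode = "coverage")$raw_value, 1)
  collapsed <- fm(matrix(rep(c(500, 500), each = 20), 20, 2))
  expect_equal(metric_knn_support(X, collapsed, mode = "recall")$raw_value, 0)
  expect_equal(metric_knn_support(X, collapsed, mode = "coverage")$raw_value, 0)
})

test_that("kNN support metrics agree exactly with the brute-force oracle", {
  set.seed(32)
  for (trial in 1:100) {
    n <- sample(5:30, 1); m <- sample(5:30, 1); d <- sample(1:3, 1)
    k <- sample(1:3, 1)
    if (min(n, m) <= k) next
    ref <- matrix(rnorm(n * d), n, d)
    syn <- matrix(rnorm(m * d, mean = runif(1, -1, 1)), m, d)
    rec <- metric_knn_support(fm(ref), fm(syn), k = k, mode = "recall")$raw_value
    expect_identical(rec, oracle_knn_fraction(syn, ref, k))
    cov <- metric_knn_support(fm(ref), fm(syn), k = k, mode = "coverage")$raw_value
    expect_identical(cov, oracle_coverage(ref, syn, k))
    prec <- metric_knn_precision(fm(ref), fm(syn), k = k)$raw_value
    expect_identical(prec, oracle_knn_fraction(ref, syn, k))
  }
})

test_that("hull ratio matches hand-computed areas and the s^2 scaling law", {
  sq <- fm(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  tri <- fm(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(metric_hull_ratio(sq, tri)$raw_value, 0.5, tolerance = 1e-9)
  expect_equal(metric_hull_ratio(sq, sq)$raw_value, 1, tolerance = 1e-12)

  set.seed(33)
  ref <- fm(matrix(rnorm(100), 50, 2))
  ctr <- colMeans(ref$values)
  for (s in c(0.3, 0.5, 0.9)) {
    shrunk <- fm(sweep(ref$values, 2, ctr) * s +
                   matrix(ctr, 50, 2, byrow = TRUE))
    expect_equal(metric_hull_ratio(ref, shrunk)$raw_value, s^2,
                 tolerance = 1e-6)
  }
  collinear <- fm(cbind(1:5, 2 * (1:5)))
  expect_error(metric_hull_ratio(sq, collinear), "degenerate")
})

test_that("Vendi score hits its extremes and matches the SVD oracle", {
  same <- fm(matrix(rep(c(1, 2), each = 8), 8, 2))
  expect_equal(metric_kernel_diversity(same, "vendi")$raw_value, 1,
               tolerance = 1e-9)
  ortho <- fm(diag(6))
  expect_equal(metric_kernel_diversity(ortho, "vendi")$raw_value, 6,
               tolerance = 1e-9)
  expect_equal(metric_kernel_diversity(ortho, "dpp_logdet")$raw_value,
               log(det(diag(6) + 1e-6 * diag(6))) / 6)

  # eigen-free oracle: exp(entropy of squared singular values / n)
  set.seed(34)
  for (trial in 1:20) {
    n <- sample(3:12, 1); d <- sample(2:6, 1)
    X <- matrix(rnorm(n * d), n, d)
    got <- metric_kernel_diversity(fm(X), "vendi")$raw_value
    U <- X / sqrt(rowSums(X^2))
    sv2 <- svd(U)$d^2 / n
    sv2 <- sv2[sv2 > 1e-14]
    want <- exp(-sum(sv2 * log(sv2)))
    expect_equal(got, want, tolerance = 1e-6)
  }
  expect_error(metric_kernel_diversity(fm(rbind(c(0, 0), c(1, 1))), "vendi"),
               "zero-norm")
})

test_that("dispersion metrics follow variance scaling and entropy extremes", {
  const <- fm(matrix(5, 10, 2))
  expect_equal(metric_dispersion(const, kind = "entropy")$raw_value, 0)

  set.seed(35)
  ref <- fm(matrix(rnorm(60), 30, 2))
  doubled <- fm(ref$values * 2)
  res <- metric_dispersion(doubled, ref, kind = "variance")
  expect_equal(res$params$ratio_to_reference, 4, tolerance = 1e-12)

  # exactly uniform over all 32 bins -> 5 bits
  u <- fm1(rep(seq(0.5 / 32, 1 - 0.5 / 32, length.out = 32), 4))
  expect_equal(metric_dispersion(u, kind = "entropy")$raw_value, 5,
               tolerance = 1e-9)
  expect_error(metric_dispersion(fm1(1), kind = "variance"), "n >= 2")
})

test_that("cluster occupancy counts reached reference modes", {
  set.seed(36)
  blob1 <- matrix(rnorm(60, 0, 0.2), 30, 2)
  blob2 <- matrix(rnorm(60, 10, 0.2), 30, 2)
  ref <- fm(rbind(blob1, blob2))
  syn_half <- fm(matrix(rnorm(60, 0, 0.2), 30, 2))  # one blob only
  res <- metric_cluster_occupancy(ref, syn_half, n_clusters = 2, seed = 5)
  expect_equal(res$raw_value, 0.5)
  full <- metric_cluster_occupancy(ref, ref, n_clusters = 2, seed = 5)
  expect_equal(full$raw_value, 1)
  expect_error(metric_cluster_occupancy(fm(matrix(0, 2, 2)), ref,
                                        n_clusters = 5), "smaller than")
})

test_that("inception-style score spans its closed-form extremes", {
  uni <- matrix(0.25, 10, 4)
  expect_equal(metric_inception_style_score(uni)$raw_value, 1)
  onehot <- diag(4)[rep(1:4, 5), ]
  expect_equal(metric_inception_style_score(onehot)$raw_value, 4,
               tolerance = 1e-12)
  same_onehot <- diag(4)[rep(1, 8), ]
  expect_equal(metric_inception_style_score(same_onehot)$raw_value, 1)
  expect_error(metric_inception_style_score(matrix(c(0.5, 0.6), 1, 2)),
               "sum 1")
})

test_that("coverage family is non-increasing as mixture components drop", {
  n_comp <- 4
  drops <- c(0, 2, 3)  # 100%, 50%, 25% of components remain
  rec <- cov_ <- occ <- hull <- numeric(length(drops))
  for (i in seq_along(drops)) {
    pair <- gen_embedding_pair(500, 3, n_components = n_comp,
                               drop_components = drops[i], seed = 77)
    rec[i] <- metric_knn_support(pair$reference, pair$synthetic,
                                 mode = "recall")$raw_value
    cov_[i] <- metric_knn_support(pair$reference, pair$synthetic,
                                  mode = "coverage")$raw_value
    occ[i] <- metric_cluster_occupancy(pair$reference, pair$synthetic,
                                       n_clusters = n_comp, seed = 5)$raw_value
    hull[i] <- metric_hull_ratio(pair$reference, pair$synthetic)$raw_value
  }
  expect_true(all(diff(rec) <= 0))
  expect_true(all(diff(cov_) <= 0))
  expect_true(all(diff(occ) <= 0))
  expect_true(all(diff(hull) <= 0))
})
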