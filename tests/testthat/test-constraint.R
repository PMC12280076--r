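test_that("interval evaluation produces exact violation depths", {
  X <- fm1(c(5, 12, -3, 0, 10))
  spec <- constraint_spec("range", target = "f1", kind = "interval",
                          lo = 0, hi = 10)
  vm <- evaluate_constraints(feature_matrix(X$values,
                                            feature_names = "f1"), spec)
  expect_equal(unname(vm$violated[, 1]), c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(vm$depth[, 1]), c(0, 2, 3, 0, 0))
})

test_that("implications fire only when the antecedent holds", {
  df <- data.frame(condition = c("anemia", "anemia", "normal"),
                   hemoglobin = c(14, 11, 14))
  td <- tabular_dataset(df)
  spec <- constraint_spec("hb-anemia", kind = "implication",
                          antecedent = list(feature = "condition",
                                            value = "anemia"),
                          consequent = list(feature = "hemoglobin",
                                            lo = 0, hi = 12))
  vm <- evaluate_constraints(td, spec)
  expect_equal(unname(vm$violated[, 1]), c(TRUE, FALSE, FALSE))
})

test_that("missing tabular values fail closed and are flagged missing-driven", {
  df <- data.frame(hb = c(10, NA, 15))
  td <- tabular_dataset(df)
  spec <- constraint_spec("hb", target = "hb", kind = "interval", lo = 0,
                          hi = 12)
  vm <- evaluate_constraints(td, spec)
  expect_equal(unname(vm$violated[, 1]), c(FALSE, TRUE, TRUE))
  expect_equal(unname(vm$missing_driven[, 1]), c(FALSE, TRUE, FALSE))
})

test_that("constraint evaluation agrees with a direct predicate oracle", {
  set.seed(41)
  for (trial in 1:10) {
    n <- 20
    df <- data.frame(a = rnorm(n), b = sample(c("x", "y", "z"), n, TRUE),
                     c = runif(n, -5, 5), stringsAsFactors = FALSE)
    lo <- runif(1, -2, 0); hi <- runif(1, 0, 2)
    allowed <- sample(c("x", "y", "z"), sample(1:2, 1))
    specs <- list(
      constraint_spec("ia", target = "a", kind = "interval", lo = lo, hi = hi),
      constraint_spec("cb", target = "b", kind = "category_set",
                      allowed = allowed),
      constraint_spec("imp", kind = "implication",
                      antecedent = list(feature = "b", value = "x"),
                      consequent = list(feature = "c", lo = 0, hi = 5))
    )
    vm <- evaluate_constraints(tabular_dataset(df), specs)
    oracle <- cbind(!(df$a >= lo & df$a <= hi),
                    !(df$b %in% allowed),
                    df$b == "x" & !(df$c >= 0 & df$c <= 5))
    expect_equal(unname(vm$violated), unname(oracle))
  }
})

test_that("violation rate counts samples violating any constraint", {
  X <- feature_matrix(matrix(c(12, 5, 20, 3, 7), ncol = 1),
                      feature_names = "x")
  spec <- constraint_spec("x", target = "x", kind = "interval", lo = 0, hi = 10)
  vm <- evaluate_constraints(X, spec)
  expect_equal(metric_violation_rate(vm)$raw_value, 0.4)
  none <- evaluate_constraints(X, list())
  expect_equal(metric_violation_rate(none)$raw_value, 0)
  all_bad <- evaluate_constraints(X, constraint_spec("neg", target = "x",
                                                     kind = "interval",
                                                     lo = -10, hi = 0))
  expect_equal(metric_violation_rate(all_bad)$raw_value, 1)
})

test_that("boundary distance averages depths and reports margins", {
  X <- feature_matrix(matrix(c(12, 5), ncol = 1), feature_names = "x")
  spec <- constraint_spec("x", target = "x", kind = "interval", lo = 0, hi = 10)
  vm <- evaluate_constraints(X, spec)
  res <- metric_boundary_distance(vm, X)
  expect_equal(res$raw_value, 1)               # (2 + 0) / 2
  expect_equal(res$params$mean_margin_satisfied, 5)

  at_bound <- feature_matrix(matrix(10, ncol = 1), feature_names = "x")
  vm2 <- evaluate_constraints(at_bound, spec)
  res2 <- metric_boundary_distance(vm2, at_bound)
  expect_equal(res2$raw_value, 0)
  expect_equal(res2$params$mean_margin_satisfied, 0)
  cat_only <- evaluate_constraints(
    tabular_dataset(data.frame(b = "x")),
    constraint_spec("b", target = "b", kind = "category_set", allowed = "x"))
  expect_error(metric_boundary_distance(cat_only), "no interval")
})

test_that("boundary distance is translation-equivariant", {
  set.seed(42)
  x <- rnorm(30, 5, 4)
  mk <- function(v, lo, hi) {
    X <- feature_matrix(matrix(v, ncol = 1), feature_names = "x")
    metric_boundary_distance(
      evaluate_constraints(X, constraint_spec("x", target = "x",
                                              kind = "interval",
                                              lo = lo, hi = hi)), X)
  }
  base <- mk(x, 0, 10)
  shifted <- mk(x + 100, 100, 110)
  expect_equal(base$raw_value, shifted$raw_value, tolerance = 1e-12)
})

test_that("nearest-invalid distance matches brute-force geometry", {
  inv <- fm(rbind(c(0, 0)))
  syn <- fm(rbind(c(3, 4)))
  expect_equal(metric_nearest_invalid(syn, inv)$raw_value, 5)

  set.seed(43)
  inv2 <- fm(matrix(rnorm(10), 5, 2))
  syn2 <- fm(matrix(rnorm(12), 6, 2))
  got <- metric_nearest_invalid(syn2, inv2)
  oracle <- mean(apply(syn2$values, 1, function(p) {
    min(sqrt(colSums((t(inv2$values) - p)^2)))
  }))
  expect_equal(got$raw_value, oracle, tolerance = 1e-12)
  expect_equal(got$params$min_distance,
               min(as.matrix(dist(rbind(syn2$values, inv2$values)))[1:6, 7:11]))
  coincide <- metric_nearest_invalid(fm(inv2$values[1, , drop = FALSE]), inv2)
  expect_equal(coincide$raw_value, 0)
})

test_that("planted image violation fractions are recovered exactly", {
  for (f in c(0, 0.2, 0.5)) {
    gen <- gen_toy_images(10, size = 48, diameter_range = c(8, 16),
                          violation_fraction = f, seed = 7)
    expect_equal(sum(gen$truth$violating), floor(f * 10))
    # constraints on the ground-truth shape features: count = 1 and
    # diameter within range
    td <- tabular_dataset(gen$truth)
    specs <- list(
      constraint_spec("count", target = "lesion_count", kind = "interval",
                      lo = 1, hi = 1),
      constraint_spec("diam", target = "lesion_diameter", kind = "interval",
                      lo = 8, hi = 16)
    )
    vm <- evaluate_constraints(td, specs)
    expect_equal(metric_violation_rate(vm)$raw_value, f)
  }
})
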