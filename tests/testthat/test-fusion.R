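test_that("fusing identical vectors reproduces them where rules allow", {
  # min, max, mean and median are idempotent everywhere; the renormalized
  # product is idempotent exactly when the vector is uniform over its
  # support, so identity holds overall for such vectors
  for (v in list(c(0.25, 0.25, 0.25, 0.25), c(0.5, 0.5, 0, 0),
                 c(1, 0, 0, 0))) {
    expect_equal(five_rule_combine(list(v, v)), v, tolerance = 1e-12)
    expect_equal(five_rule_combine(list(v, v, v)), v, tolerance = 1e-12)
    expect_equal(fuse_repetitions(v, v), v, tolerance = 1e-12)
    expect_equal(fuse_vocalizations(v, v, v), v, tolerance = 1e-12)
  }
  # on general vectors the combination of n copies still matches the
  # oracle, and the four order/mean rules are each idempotent
  set.seed(9)
  for (i in 1:20) {
    v <- random_simplex()
    M <- cbind(v, v, v)
    expect_equal(apply(M, 1, min), v, tolerance = 1e-12)
    expect_equal(apply(M, 1, max), v, tolerance = 1e-12)
    expect_equal(rowMeans(M), v, tolerance = 1e-12)
    expect_equal(apply(M, 1, median), v, tolerance = 1e-12)
    expect_equal(five_rule_combine(list(v, v, v)),
                 oracle_five_rule(list(v, v, v)), tolerance = 1e-12)
  }
})

test_that("the product rule renormalizes as in the worked example", {
  v <- c(0.5, 0.5, 0, 0)
  # product gives (0.25, 0.25, 0, 0) which renormalizes back to v; all
  # other rules return v directly, so the fused output is v
  expect_equal(five_rule_combine(list(v, v)), v, tolerance = 1e-12)
})

test_that("fusion matches the brute-force oracle on random inputs", {
  set.seed(10)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    vs <- replicate(k, random_simplex(), simplify = FALSE)
    expect_equal(five_rule_combine(vs), oracle_five_rule(vs),
                 tolerance = 1e-12)
  }
  # the documented two-vector example
  a <- c(0.4, 0.3, 0.2, 0.1); b <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(five_rule_combine(list(a, b)),
               oracle_five_rule(list(a, b)), tolerance = 1e-12)
})

test_that("fusion is permutation invariant and closed over the simplex", {
  set.seed(11)
  for (i in 1:50) {
    vs <- replicate(3, random_simplex(), simplify = FALSE)
    out1 <- five_rule_combine(vs)
    out2 <- five_rule_combine(vs[c(3, 1, 2)])
    expect_equal(out1, out2, tolerance = 1e-12)
    expect_true(all(out1 >= 0))
    expect_equal(sum(out1), 1, tolerance = 1e-12)
  }
})

test_that("fused components stay within the per-rule envelope", {
  set.seed(12)
  for (i in 1:50) {
    vs <- replicate(2, random_simplex(), simplify = FALSE)
    M <- do.call(cbind, vs)
    rules <- cbind(apply(M, 1, min), apply(M, 1, max), rowMeans(M),
                   apply(M, 1, median), apply(M, 1, prod))
    rules <- sweep(rules, 2, colSums(rules), `/`)
    out <- five_rule_combine(vs)
    expect_true(all(out >= apply(rules, 1, min) - 1e-12))
    expect_true(all(out <= apply(rules, 1, max) + 1e-12))
  }
})

test_that("missing repetitions and ablation subsets pass through", {
  v <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(fuse_repetitions(v, NULL), v, tolerance = 1e-12)
  expect_equal(fuse_repetitions(NULL, v), v, tolerance = 1e-12)
  expect_error(fuse_repetitions(NULL, NULL))
  expect_equal(fuse_vocalizations(ae = v), v, tolerance = 1e-12)
  w <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(fuse_vocalizations(ae = v, sa = w),
               oracle_five_rule(list(v, w)), tolerance = 1e-12)
  expect_error(fuse_vocalizations())
})

test_that("feature-kind fusion is the simple average", {
  expect_equal(fuse_feature_types(c(1, 0, 0, 0), c(0, 1, 0, 0)),
               c(0.5, 0.5, 0, 0), tolerance = 1e-12)
  v <- c(0.25, 0.25, 0.3, 0.2)
  expect_equal(fuse_feature_types(v, v), v, tolerance = 1e-12)
  expect_equal(fuse_feature_types(v, NULL), v, tolerance = 1e-12)
})

test_that("averaging cannot invent a new top class except on ties", {
  # coarse simplex grid: all compositions of 4 in steps of 0.25
  grid <- list()
  for (a in seq(0, 1, 0.25)) for (b in seq(0, 1 - a, 0.25)) {
    for (c0 in seq(0, 1 - a - b, 0.25)) {
      grid[[length(grid) + 1]] <- c(a, b, c0, 1 - a - b - c0)
    }
  }
  top <- function(v) which(v == max(v))
  violations <- 0L
  for (u in grid) for (w in grid) {
    out <- fuse_feature_types(u, w)
    shared_top <- intersect(top(out), union(top(u), top(w)))
    if (length(shared_top) == 0 && length(top(u)) + length(top(w)) <= 2) {
      violations <- violations + 1L
    }
  }
  expect_gt(length(grid), 30)
  expect_identical(violations, 0L)
})

test_that("the final decision is the argmax with ties to the lower class", {
  expect_identical(predict_mmrc(c(0.1, 0.2, 0.6, 0.1)), 2L)
  expect_identical(predict_mmrc(c(0.25, 0.25, 0.25, 0.25)), 0L)
  expect_identical(predict_mmrc(c(0, 0, 0, 1)), 3L)
  expect_identical(predict_mmrc(c(0.1, 0.4, 0.4, 0.1)), 1L)
})
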