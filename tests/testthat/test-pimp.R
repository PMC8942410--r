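## A cheap refitting recipe (plain forest importance, no clustering
## structure) keeps the permutation tests fast while exercising the exact
## p-value machinery.
forest_spec <- function(num_trees = 60) {
  function(X, y, clusters, seed) {
    rf <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                         importance = "permutation", seed = seed,
                         num.threads = 1)
    rf$variable.importance
  }
}

test_that("a dominant feature attains the minimum attainable p-value", {
  set.seed(3)
  n <- 120
  X <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- 3 * X$signal + rnorm(n, 0, 0.3)
  cl <- rep(1:12, each = 10)
  res <- pimp(forest_spec(), X, y, cl, n_perm = 99, seed = 4)
  expect_equal(res$p_value[res$feature == "signal"], 1 / 100)
  expect_true(all(res$p_value >= 1 / 100))
  expect_equal(nrow(attr(res, "null_importances")), 99)
  expect_error(pimp(forest_spec(), X, y, cl, n_perm = 10), ">= 19")
})

test_that("a constant feature is unimportant with p near 1", {
  set.seed(5)
  n <- 100
  X <- data.frame(flat = rep(1, n), x = rnorm(n))
  y <- X$x + rnorm(n, 0, 0.5)
  res <- pimp(forest_spec(), X, y, rep(1:10, each = 10), n_perm = 49, seed = 6)
  expect_lt(abs(res$observed_importance[res$feature == "flat"]), 1e-8)
  expect_gt(res$p_value[res$feature == "flat"], 0.5)
})

test_that("p-values are feature-order invariant and q preserves p ranks", {
  ## a column-order-invariant importance (|correlation| per feature) isolates
  ## the PIMP machinery itself: permutations and p-values must not depend on
  ## how the features happen to be ordered
  cor_spec <- function(X, y, clusters, seed) {
    vapply(X, function(v) abs(stats::cor(v, y)), numeric(1))
  }
  set.seed(7)
  n <- 80
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- X$a + 0.5 * X$b + rnorm(n)
  cl <- rep(1:8, each = 10)
  r1 <- pimp(cor_spec, X, y, cl, n_perm = 29, seed = 9)
  r2 <- pimp(cor_spec, X[c("c", "a", "b")], y, cl, n_perm = 29, seed = 9)
  expect_equal(r1$p_value[match(r2$feature, r1$feature)], r2$p_value)
  ## q sorted by p is non-decreasing, and never below p's BH floor
  expect_true(all(diff(r1$q_value[order(r1$p_value)]) >= -1e-12))
  expect_true(all(r1$q_value >= r1$p_value))
})

test_that("within-subject permutation preserves cluster multisets", {
  y <- c(1, 2, 3, 10, 20, 30)
  cl <- c("a", "a", "a", "b", "b", "b")
  set.seed(11)
  for (i in 1:20) {
    yp <- dietshift:::permute_response(y, cl, "within-subject")
    expect_setequal(yp[1:3], y[1:3])
    expect_setequal(yp[4:6], y[4:6])
  }
})

test_that("BH adjustment matches hand execution of the step-up rule", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 4)), rep(1, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.1, 1.1)), "\\[0, 1\\]")
})
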