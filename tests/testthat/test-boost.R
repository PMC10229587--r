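test_that("split improvement follows the weighted between-child formula", {
  expect_equal(split_improvement(1, 1, 1, 0), 0.5)
  expect_equal(split_improvement(2, 2, 4, 1), 9)
  expect_equal(split_improvement(3, 7, 2, 2), 0)
  expect_equal(split_improvement(1, 3, 0, 2), split_improvement(3, 1, 2, 0))
  expect_error(split_improvement(0, 1, 1, 0), "positive")
  expect_error(split_improvement(1, -1, 1, 0), "positive")
})

test_that("pseudoresponses and weights follow the Newton step", {
  pr <- pseudoresponse_and_weight(1, 0.5)
  expect_equal(pr$ybar, 1)
  expect_equal(pr$w, 0.25)
  expect_equal(pseudoresponse_and_weight(0, 0.5)$ybar, -1)
  # weight is maximal at p = 0.5
  ps <- seq(0.05, 0.95, by = 0.05)
  ws <- vapply(ps, function(p) pseudoresponse_and_weight(1, p)$w, numeric(1))
  expect_equal(ps[which.max(ws)], 0.5)
  # clipping keeps the degenerate probabilities finite
  expect_true(is.finite(pseudoresponse_and_weight(1, 0)$ybar))
  expect_true(is.finite(pseudoresponse_and_weight(0, 1)$ybar))
})

test_that("boosting separates separable data and stays on the probability scale", {
  set.seed(3)
  X <- matrix(c(rnorm(60, 0), rnorm(60, 5)), ncol = 1)
  y <- rep(c(0L, 1L), each = 60)
  m <- fit_boosting(X, y, boost_control(n_trees = 20, depth = 1))
  p <- predict(m, X)
  expect_true(all(p > 0 & p < 1))
  expect_equal(mean((p > 0.5) == (y == 1L)), 1)
  expect_true(all(diff(m$logloss) <= 1e-8))
  expect_error(fit_boosting(X, rep(1L, 120)), "both classes")
})

test_that("boosting fits are deterministic", {
  pb <- planted_problem(200, 5, informative = 2, shift = 1.5,
                        n_patients = 10, seed = 9)
  m1 <- fit_boosting(pb$X, pb$y, boost_control(n_trees = 10))
  m2 <- fit_boosting(pb$X, pb$y, boost_control(n_trees = 10))
  expect_identical(m1$logloss, m2$logloss)
  expect_identical(model_relevance(m1), model_relevance(m2))
})

test_that("tree relevance tallies split improvements per variable", {
  stump <- list(var = c(3L, 0L, 0L), improvement = c(4, 0, 0))
  expect_equal(tree_relevance(stump, 5), c(0, 0, 4, 0, 0))
  # conservation on fitted trees, against an independent node walk
  pb <- planted_problem(150, 6, informative = c(1, 4), shift = 1.2,
                        n_patients = 10, seed = 5)
  m <- fit_boosting(pb$X, pb$y, boost_control(n_trees = 5))
  for (tr in c(m$trees1, m$trees2)) {
    rel <- tree_relevance(tr, 6)
    internal <- tr$var > 0L
    expect_equal(sum(rel), sum(tr$improvement[internal]), tolerance = 1e-12)
    # oracle: per-variable sums recomputed independently
    oracle <- vapply(1:6, function(j) {
      sum(tr$improvement[internal & tr$var == j])
    }, numeric(1))
    expect_equal(rel, oracle, tolerance = 1e-9)
    expect_true(all(tr$improvement >= 0))
  }
})

test_that("model relevance is scaled to 100 and finds the signal", {
  # only one feature can ever be split on
  set.seed(2)
  X <- cbind(F1 = rnorm(100), F2 = rep(0, 100), F3 = rep(0, 100))
  y <- as.integer(X[, 1] > 0)
  m <- fit_boosting(X, y, boost_control(n_trees = 10, depth = 1))
  tab <- model_relevance(m)
  expect_equal(tab$relevance[1], 100)
  expect_equal(tab$relevance[2:3], c(0, 0))
  expect_true(all(tab$relevance >= 0 & tab$relevance <= 100))
  pb <- planted_problem(300, 8, informative = 6, shift = 2, n_patients = 10,
                        seed = 31)
  tab2 <- model_relevance(fit_boosting(pb$X, pb$y))
  expect_equal(which.max(tab2$relevance), 6L)
})
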