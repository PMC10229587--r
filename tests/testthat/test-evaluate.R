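test_that("patient folds are disjoint and balanced", {
  plan40 <- make_patient_folds(sprintf("p%02d", 1:40), 5, seed = 1)
  expect_true(all(table(plan40$fold) == 8L))
  plan17 <- make_patient_folds(sprintf("p%02d", 1:17), 5, seed = 1)
  expect_identical(sort(as.integer(table(plan17$fold)), decreasing = TRUE),
                   c(4L, 4L, 3L, 3L, 3L))
  for (seed in 1:10) {
    plan <- make_patient_folds(sprintf("p%02d", 1:12), 5, seed = seed)
    expect_identical(anyDuplicated(plan$patient), 0L)
    expect_setequal(plan$patient, sprintf("p%02d", 1:12))
  }
  expect_error(make_patient_folds(c("a", "b"), 5), "fewer")
})

test_that("KNN votes with Euclidean distance and conservative ties", {
  train <- matrix(c(0, 0, 1, 1, 5, 5, 6, 6), ncol = 2, byrow = TRUE)
  labels <- c(0L, 0L, 1L, 1L)
  # K = 1 on an exact training point returns its label
  expect_identical(knn_classify(train, labels, train, k = 1),
                   labels)
  # well-separated clusters: perfect for any K up to the cluster size
  set.seed(4)
  tr <- rbind(matrix(rnorm(100, 0, 0.2), ncol = 2),
              matrix(rnorm(100, 8, 0.2), ncol = 2))
  yy <- rep(c(0L, 1L), each = 50)
  qu <- rbind(matrix(rnorm(20, 0, 0.2), ncol = 2),
              matrix(rnorm(20, 8, 0.2), ncol = 2))
  for (k in c(1, 15, 49)) {
    expect_identical(knn_classify(tr, yy, qu, k), rep(c(0L, 1L), each = 10))
  }
  # K = n on a 70/30 mix: constant majority label
  set.seed(5)
  tr2 <- matrix(rnorm(200), ncol = 2)
  y2 <- rep(c(0L, 1L), times = c(70, 30))
  expect_true(all(knn_classify(tr2, y2, qu, k = 100) == 0L))
  # exact vote tie goes to non-shockable
  tie <- knn_classify(matrix(c(-1, 1), ncol = 1), c(0L, 1L),
                      matrix(0, ncol = 1), k = 2)
  expect_identical(tie, 0L)
  expect_error(knn_classify(tr, yy, qu, k = 999), "exceeds")
})

test_that("metrics reproduce the published arithmetic", {
  expect_equal(balanced_error_rate(97.69, 99.71), 1.30)
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(m$Ac, 100)
  expect_equal(m$BER, 0)
  m2 <- compute_metrics(rep(0, 10), c(rep(0, 6), rep(1, 4)))
  expect_equal(m2$Se, 0)
  expect_equal(m2$Sp, 100)
  expect_equal(m2$BER, 50)
  expect_error(compute_metrics(c(0, 1), c(1, 1)), "negative")
  expect_error(compute_metrics(c(0, 1), c(0, 0)), "positive")
})

test_that("the BER identity holds for arbitrary confusions", {
  set.seed(6)
  for (i in 1:50) {
    n <- 40
    labels <- c(0L, 1L, rbinom(n - 2, 1, 0.4))
    preds <- rbinom(n, 1, 0.5)
    m <- compute_metrics(preds, labels)
    expect_lt(abs(m$BER / 100 - (1 - 0.5 * (m$Se + m$Sp) / 100)), 1e-12)
  }
})

test_that("repeated CV is deterministic, leak-free and perfect on easy data", {
  fm <- small_features()
  cv <- repeated_cv(fm, FEATURE_NAMES, k = 15, n_folds = 5, n_reps = 2,
                    seed = 3)
  expect_equal(nrow(cv$reps), 2L)
  cv2 <- repeated_cv(fm, FEATURE_NAMES, k = 15, n_folds = 5, n_reps = 2,
                     seed = 3)
  expect_identical(cv$reps, cv2$reps)
  expect_equal(unname(cv$mean["Ac"]), 100)
  expect_equal(unname(cv$mean["Se"]), 100)
  expect_equal(unname(cv$mean["Sp"]), 100)
  expect_equal(unname(cv$sd["Ac"]), 0)
  # per-fold averaging agrees on a perfect classifier
  cvf <- repeated_cv(fm, FEATURE_NAMES, k = 15, n_reps = 1, seed = 3,
                     pool = FALSE)
  expect_equal(unname(cvf$mean["Ac"]), 100)
})

test_that("label corruption degrades accuracy by about the corruption rate", {
  fm <- small_features()
  q <- 0.1
  fmq <- fm
  set.seed(11)
  flip <- sample(nrow(fm), round(q * nrow(fm)))
  fmq$label[flip] <- 1L - fmq$label[flip]
  cv <- repeated_cv(fmq, FEATURE_NAMES, k = 15, n_reps = 3, seed = 4)
  expect_lt(abs(unname(cv$mean["Ac"]) - 100 * (1 - q)), 5)
})

test_that("K selection scans the grid with smallest-K tie-breaking", {
  fm <- small_features()
  sel <- select_k(fm, FEATURE_NAMES, k_grid = c(5, 10, 15, 20), seed = 2)
  expect_true(sel$k %in% c(5, 10, 15, 20))
  # easy cohort: many K tie at 100% -> smallest returned
  expect_equal(sel$k, 5)
  expect_equal(sel$accuracy, 100)
  expect_error(select_k(fm, FEATURE_NAMES, k_grid = integer(0)), ".")
})

test_that("grid search is an exhaustive argmax consistent with select_k", {
  fm <- small_features()
  cands <- list(list(subset = FEATURE_NAMES, k = 5),
                list(subset = c("MAva", "Kurt"), k = 15))
  gs <- grid_search(fm, cands, seed = 2)
  expect_true(gs$index %in% 1:2)
  expect_true(all(gs$scores[gs$index] >= gs$scores))
  one <- grid_search(fm, cands[1], seed = 2)
  expect_identical(one$index, 1L)
  expect_error(grid_search(fm, list()), "empty")
})
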