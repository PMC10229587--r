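# Two-ensemble gradient boosting for binary classification, built for its
# split-improvement variable relevance. One weighted regression tree per
# class is grown at each round on the Newton pseudoresponses; class
# probabilities come from a softmax over the two additive ensembles. Every
# internal node stores its split variable and improvement
# s2 = w1*w2/(w1+w2) * (ybar1 - ybar2)^2, the quantity later tallied into
# per-feature relevance.

#' Split improvement of a candidate binary partition
#'
#' `s2 = w1*w2/(w1+w2) * (ybar1 - ybar2)^2`: the reduction in weighted
#' squared error obtained by fitting separate constants to the two daughter
#' regions. Symmetric in the two daughters.
#'
#' @param w1,w2 Positive daughter weight sums.
#' @param ybar1,ybar2 Daughter mean responses.
#' @return Non-negative scalar.
#' @export
split_improvement <- function(w1, w2, ybar1, ybar2) {
  if (any(c(w1, w2) <= 0)) stop("weights must be positive", call. = FALSE)
  w1 * w2 / (w1 + w2) * (ybar1 - ybar2)^2
}

#' Newton pseudoresponse and weight for one observation
#'
#' `ybar = ((K-1)/K) * (y - p) / (p * (1 - p))` and `w = p * (1 - p)` with
#' `K = n_classes` (1/2 leading factor for binary problems). Probabilities
#' are clipped to `[eps, 1 - eps]`.
#'
#' @param y Class indicator in {0, 1}.
#' @param p Predicted class probability.
#' @param n_classes Number of classes.
#' @param eps Clipping bound for `p`.
#' @return `list(ybar, w)`.
#' @export
pseudoresponse_and_weight <- function(y, p, n_classes = 2, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  w <- p * (1 - p)
  list(ybar = ((n_classes - 1) / n_classes) * (y - p) / w, w = w)
}

#' Boosting hyperparameters
#'
#' @param n_trees Trees per class ensemble (boosting rounds).
#' @param depth Maximum tree depth.
#' @param learning_rate Shrinkage applied to each tree.
#' @param min_leaf Minimum samples per leaf.
#' @return A `boost_control` list.
#' @export
boost_control <- function(n_trees = 100L, depth = 3L, learning_rate = 0.1,
                          min_leaf = 5L) {
  structure(list(n_trees = as.integer(n_trees), depth = as.integer(depth),
                 learning_rate = learning_rate, min_leaf = as.integer(min_leaf)),
            class = "boost_control")
}

fit_one_tree <- function(X, ybar, w, control) {
  tr <- fit_wls_tree_cpp(X, ybar, w, control$depth, control$min_leaf)
  tr$var <- tr$var + 1L  # 1-based; 0 marks a leaf
  tr
}

predict_one_tree <- function(tree, X) {
  predict_wls_tree_cpp(tree$var - 1L, tree$threshold, tree$value,
                       tree$left, tree$right, X)
}

#' Fit the two-ensemble boosting model
#'
#' @param X Numeric matrix (or data.frame) of features.
#' @param y Binary labels in {0, 1}.
#' @param control A [boost_control()].
#' @param seed Kept for interface symmetry; the fit is deterministic (no
#'   subsampling), so the seed does not alter the result.
#' @return A `boosted_trees` model with ensembles `trees1` (class 0) and
#'   `trees2` (class 1), feature names, and the training log-loss per round.
#' @export
fit_boosting <- function(X, y, control = boost_control(), seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("`y` must contain both classes", call. = FALSE)
  }
  n <- nrow(X)
  y1 <- as.numeric(y == 0L)  # class t1 indicator
  y2 <- as.numeric(y == 1L)
  f1 <- numeric(n)
  f2 <- numeric(n)
  trees1 <- vector("list", control$n_trees)
  trees2 <- vector("list", control$n_trees)
  logloss <- numeric(control$n_trees)
  for (l in seq_len(control$n_trees)) {
    e1 <- exp(f1 - pmax(f1, f2))
    e2 <- exp(f2 - pmax(f1, f2))
    p1 <- e1 / (e1 + e2)
    p2 <- 1 - p1
    pr1 <- pseudoresponse_and_weight(y1, p1)
    trees1[[l]] <- fit_one_tree(X, pr1$ybar, pr1$w, control)
    f1 <- f1 + control$learning_rate * predict_one_tree(trees1[[l]], X)
    pr2 <- pseudoresponse_and_weight(y2, p2)
    trees2[[l]] <- fit_one_tree(X, pr2$ybar, pr2$w, control)
    f2 <- f2 + control$learning_rate * predict_one_tree(trees2[[l]], X)
    e1 <- exp(f1 - pmax(f1, f2)); e2 <- exp(f2 - pmax(f1, f2))
    p2 <- e2 / (e1 + e2)
    p2c <- pmin(pmax(p2, 1e-12), 1 - 1e-12)
    logloss[l] <- -mean(y2 * log(p2c) + (1 - y2) * log(1 - p2c))
  }
  structure(list(trees1 = trees1, trees2 = trees2,
                 feature_names = colnames(X) %||%
                   paste0("F", seq_len(ncol(X))),
                 n_features = ncol(X), control = control, logloss = logloss),
            class = "boosted_trees")
}

#' Predict shockable-class probabilities from a boosting model
#' @param object A `boosted_trees` model.
#' @param X Feature matrix.
#' @param ... Unused.
#' @return Probabilities of class 1 in (0, 1).
#' @export
predict.boosted_trees <- function(object, X, ...) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  f1 <- numeric(nrow(X))
  f2 <- numeric(nrow(X))
  lr <- object$control$learning_rate
  for (tr in object$trees1) f1 <- f1 + lr * predict_one_tree(tr, X)
  for (tr in object$trees2) f2 <- f2 + lr * predict_one_tree(tr, X)
  m <- pmax(f1, f2)
  exp(f2 - m) / (exp(f1 - m) + exp(f2 - m))
}

#' Per-feature relevance of a single tree
#'
#' Sums the stored split improvements over the internal nodes that split on
#' each feature; the vector total equals the sum of improvements over all
#' internal nodes.
#'
#' @param tree One tree from a `boosted_trees` ensemble.
#' @param n_features Length of the output vector.
#' @return Numeric vector of squared relevances.
#' @export
tree_relevance <- function(tree, n_features) {
  out <- numeric(n_features)
  internal <- which(tree$var > 0L)
  for (i in internal) {
    out[tree$var[i]] <- out[tree$var[i]] + tree$improvement[i]
  }
  out
}

#' Model-level feature importance
#'
#' Averages squared per-tree relevances within each class ensemble, averages
#' the two ensembles, takes square roots, and rescales so the maximum is
#' 100 (ties broken by feature-name order when identifying the maximum).
#'
#' @param model A `boosted_trees` model.
#' @return `data.frame(feature, relevance, raw)` in feature order:
#'   `relevance` on the 0--100 scale, `raw` the unscaled square root.
#' @export
model_relevance <- function(model) {
  p <- model$n_features
  r1 <- rowMeans(vapply(model$trees1, tree_relevance, numeric(p),
                        n_features = p))
  r2 <- rowMeans(vapply(model$trees2, tree_relevance, numeric(p),
                        n_features = p))
  raw <- sqrt(0.5 * (r1 + r2))
  mx <- max(raw)
  scaled <- if (mx > 0) 100 * raw / mx else rep(0, p)
  data.frame(feature = model$feature_names, relevance = scaled, raw = raw,
             stringsAsFactors = FALSE)
}
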