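# Component feature combination (CFC): standardization on training
# statistics followed by eigendecomposition of the correlation matrix.
# All components are retained (feature count = component count), so the
# transform is invertible and the eigenvalues sum to the feature count.

#' Standardize a feature matrix
#'
#' Columns are centred and scaled with training statistics; zero-variance
#' columns get `sd = 1` (with a warning) and contribute a zero-variance
#' component.
#'
#' @param X Numeric matrix or data.frame.
#' @param means,sds Optional pre-computed statistics (e.g. from training
#'   data); computed from `X` when `NULL`.
#' @return `list(Z, means, sds)`.
#' @export
standardize <- function(X, means = NULL, sds = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L && is.null(means)) {
    stop("need at least 2 rows to estimate standardization statistics",
         call. = FALSE)
  }
  if (is.null(means)) means <- colMeans(X)
  if (is.null(sds)) {
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) {
      warning("zero-variance feature(s): ",
              paste(colnames(X)[sds == 0], collapse = ", "),
              "; sd replaced by 1", call. = FALSE)
      sds[sds == 0] <- 1
    }
  }
  Z <- sweep(sweep(X, 2, means, "-"), 2, sds, "/")
  list(Z = Z, means = means, sds = sds)
}

#' Fit the component feature combination model
#'
#' Standardizes on the training data, builds the correlation matrix,
#' eigendecomposes it, sorts eigenpairs by descending eigenvalue and fixes
#' each loading column's sign so its largest-magnitude entry is positive
#' (first index on ties).
#'
#' @param X_train Training feature matrix (columns named).
#' @return A `cfc_model`: feature names, training means/sds, `loadings`
#'   (columns = eigenvectors), `eigenvalues` (descending, summing to the
#'   feature count).
#' @export
fit_cfc <- function(X_train) {
  X_train <- as.matrix(X_train)
  if (any(!is.finite(X_train))) {
    stop("non-finite entries in the training matrix", call. = FALSE)
  }
  if (is.null(colnames(X_train))) {
    colnames(X_train) <- paste0("F", seq_len(ncol(X_train)))
  }
  st <- standardize(X_train)
  R <- cor(sweep(sweep(X_train, 2, st$means, "-"), 2, st$sds, "/"))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  eg <- eigen(R, symmetric = TRUE)
  ord <- order(eg$values, decreasing = TRUE)
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(X_train),
                         paste0("C", seq_len(ncol(vecs))))
  structure(list(feature_names = colnames(X_train), means = st$means,
                 sds = st$sds, loadings = vecs, eigenvalues = vals),
            class = "cfc_model")
}

#' @export
print.cfc_model <- function(x, ...) {
  cat(sprintf("<cfc_model> %d features; leading eigenvalues: %s\n",
              length(x$feature_names),
              paste(sprintf("%.3f", head(x$eigenvalues, 4)), collapse = ", ")))
  invisible(x)
}

#' Project data onto the component feature combination
#'
#' Standardizes with the stored training statistics and projects onto all
#' loading columns (no truncation). Transforming held-out data never
#' updates the stored statistics.
#'
#' @param model A [fit_cfc()] model.
#' @param X Data with (at least) the model's feature columns.
#' @return Score matrix, one column per component.
#' @export
transform_cfc <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) == length(model$feature_names)) {
    colnames(X) <- model$feature_names
  }
  missing <- setdiff(model$feature_names, colnames(X))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- X[, model$feature_names, drop = FALSE]
  Z <- sweep(sweep(X, 2, model$means, "-"), 2, model$sds, "/")
  Z %*% model$loadings
}

#' Map component scores back to feature space
#'
#' The exact inverse of [transform_cfc()] for the full component set:
#' de-standardized feature values; zero scores map to the training means.
#'
#' @param model A [fit_cfc()] model.
#' @param scores Score matrix with one column per component.
#' @return Feature-space matrix.
#' @export
inverse_cfc <- function(model, scores) {
  scores <- as.matrix(scores)
  Z <- scores %*% t(model$loadings)
  sweep(sweep(Z, 2, model$sds, "*"), 2, model$means, "+")
}
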