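# KNN classification on CFC scores and patient-wise cross-validated
# evaluation. Folds are disjoint at the patient level; standardization and
# PCA are refitted inside every training fold so no held-out information
# leaks into the transform. Metrics use shockable (label 1) as the positive
# class and are reported as percentages.

#' Patient-wise fold plan
#'
#' Patients are shuffled under `seed` and dealt round-robin into folds, so
#' fold sizes in patients differ by at most one (segment counts may differ
#' more, since patients contribute unequal numbers of segments).
#'
#' @param patient_ids Patient identifier per segment (or the unique IDs).
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return A `fold_plan`: `data.frame(patient, fold)` with attributes
#'   `n_folds` and `seed`.
#' @export
make_patient_folds <- function(patient_ids, n_folds = 5, seed = 1L) {
  patients <- unique(as.character(patient_ids))
  if (length(patients) < n_folds) {
    stop("fewer distinct patients (", length(patients), ") than folds (",
         n_folds, ")", call. = FALSE)
  }
  shuffled <- with_local_seed(seed, sample(patients))
  structure(data.frame(patient = shuffled,
                       fold = rep_len(seq_len(n_folds), length(shuffled)),
                       stringsAsFactors = FALSE),
            n_folds = n_folds, seed = seed,
            class = c("fold_plan", "data.frame"))
}

#' K-nearest-neighbour classification
#'
#' Euclidean distance, unweighted majority vote; an exact vote tie is
#' broken toward label 0 (non-shockable).
#'
#' @param train_scores Training score matrix.
#' @param train_labels Binary labels in {0, 1}.
#' @param query_scores Query score matrix (same columns).
#' @param k Neighbourhood size, at most `nrow(train_scores)`.
#' @return Integer vector of 0/1 predictions.
#' @export
knn_classify <- function(train_scores, train_labels, query_scores, k = 15) {
  train_scores <- as.matrix(train_scores)
  query_scores <- as.matrix(query_scores)
  if (nrow(train_scores) == 0L) stop("empty training set", call. = FALSE)
  if (k > nrow(train_scores)) {
    stop("`k` exceeds the number of training samples", call. = FALSE)
  }
  tn2 <- rowSums(train_scores^2)
  cross <- query_scores %*% t(train_scores)
  qn2 <- rowSums(query_scores^2)
  d2 <- sweep(-2 * cross, 2, tn2, "+") + qn2
  apply(d2, 1, function(d) {
    nn <- order(d)[seq_len(k)]
    as.integer(mean(train_labels[nn]) > 0.5)
  })
}

#' Balanced error rate from printed sensitivity and specificity
#'
#' `BER = 1 - 0.5 * (Se + Sp)` on the fraction scale; inputs and output
#' are percentages.
#'
#' @param se_percent Sensitivity in percent.
#' @param sp_percent Specificity in percent.
#' @return BER in percent.
#' @export
balanced_error_rate <- function(se_percent, sp_percent) {
  100 - (se_percent + sp_percent) / 2
}

#' Classification metrics
#'
#' Accuracy, sensitivity, specificity and balanced error rate (all in
#' percent) with the confusion counts; shockable (1) is the positive class.
#'
#' @param predictions Predicted 0/1 labels.
#' @param labels True 0/1 labels; both classes must be present.
#' @return A `saa_metrics` list: `Ac`, `Se`, `Sp`, `BER`, `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
compute_metrics <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  if (!any(labels == 1L)) stop("no positive examples: Se undefined",
                               call. = FALSE)
  if (!any(labels == 0L)) stop("no negative examples: Sp undefined",
                               call. = FALSE)
  tp <- sum(predictions == 1L & labels == 1L)
  tn <- sum(predictions == 0L & labels == 0L)
  fp <- sum(predictions == 1L & labels == 0L)
  fn <- sum(predictions == 0L & labels == 1L)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  structure(list(Ac = 100 * (tp + tn) / length(labels), Se = 100 * se,
                 Sp = 100 * sp, BER = 100 * (1 - 0.5 * (se + sp)),
                 TP = tp, TN = tn, FP = fp, FN = fn),
            class = "saa_metrics")
}

#' @export
print.saa_metrics <- function(x, ...) {
  cat(sprintf("Ac %.2f%%  Se %.2f%%  Sp %.2f%%  BER %.2f%%\n",
              x$Ac, x$Se, x$Sp, x$BER))
  invisible(x)
}

# Fit-and-score one fold: standardize + PCA on the training rows only,
# KNN on the component scores. Structural leakage guard included.
fold_predict <- function(features_df, subset, fold_of, f, k) {
  tr <- fold_of != f
  te <- !tr
  stopifnot(length(intersect(unique(features_df$patient_id[tr]),
                             unique(features_df$patient_id[te]))) == 0L)
  cfc <- fit_cfc(features_df[tr, subset, drop = FALSE])
  str_scores <- transform_cfc(cfc, features_df[tr, subset, drop = FALSE])
  ste_scores <- transform_cfc(cfc, features_df[te, subset, drop = FALSE])
  k_eff <- min(k, nrow(str_scores))
  list(pred = knn_classify(str_scores, features_df$label[tr], ste_scores,
                           k_eff),
       truth = features_df$label[te], test_idx = which(te))
}

#' Repeated patient-wise cross-validation of the standardize-PCA-KNN stack
#'
#' For each repetition a new patient-wise fold plan is drawn; for each fold
#' the full per-fold pipeline (standardize, PCA, KNN) is fitted on the
#' training folds and evaluated on the held-out fold. By default the
#' predictions of the folds within one repetition are pooled before the
#' metrics are computed (`pool = FALSE` averages per-fold metrics instead).
#'
#' @param features_df Feature matrix as returned by
#'   [extract_feature_matrix()] (needs `patient_id`, `label` and the
#'   feature columns).
#' @param subset Character vector of feature columns to use.
#' @param k KNN neighbourhood size.
#' @param n_folds Patient-wise folds.
#' @param n_reps Repetitions.
#' @param seed Master seed.
#' @param pool Pool predictions across folds before computing metrics.
#' @return A `cv_result`: per-metric mean and sd over repetitions plus the
#'   per-repetition raw metrics.
#' @export
repeated_cv <- function(features_df, subset, k = 15, n_folds = 5,
                        n_reps = 30, seed = 1L, pool = TRUE) {
  seeds <- derive_seeds(seed, n_reps)
  metric_names <- c("Ac", "Se", "Sp", "BER")
  reps <- matrix(NA_real_, n_reps, 4, dimnames = list(NULL, metric_names))
  for (rep in seq_len(n_reps)) {
    plan <- make_patient_folds(features_df$patient_id, n_folds, seeds[rep])
    fold_of <- plan$fold[match(features_df$patient_id, plan$patient)]
    if (pool) {
      pred <- integer(nrow(features_df))
      for (f in seq_len(n_folds)) {
        fp <- fold_predict(features_df, subset, fold_of, f, k)
        pred[fp$test_idx] <- fp$pred
      }
      m <- compute_metrics(pred, features_df$label)
      reps[rep, ] <- c(m$Ac, m$Se, m$Sp, m$BER)
    } else {
      per_fold <- vapply(seq_len(n_folds), function(f) {
        fp <- fold_predict(features_df, subset, fold_of, f, k)
        m <- compute_metrics(fp$pred, fp$truth)
        c(m$Ac, m$Se, m$Sp, m$BER)
      }, numeric(4))
      reps[rep, ] <- rowMeans(per_fold)
    }
  }
  means <- colMeans(reps)
  sds <- apply(reps, 2, sd)
  structure(list(mean = means, sd = sds, reps = reps, n_folds = n_folds,
                 n_reps = n_reps, k = k, subset = subset, pool = pool),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d reps, K=%d, %d features\n",
              x$n_folds, x$n_reps, x$k, length(x$subset)))
  for (m in names(x$mean)) {
    cat(sprintf("  %-3s %.2f +- %.2f\n", m, x$mean[m], x$sd[m]))
  }
  invisible(x)
}

#' Select the KNN neighbourhood size by patient-wise CV accuracy
#'
#' Evaluates every `k` in the grid on one patient-wise fold plan (the
#' fold-wise component scores are computed once and reused across the
#' grid); ties are broken toward the smallest `k`.
#'
#' @param features_df Feature matrix (see [repeated_cv()]).
#' @param subset Feature columns to use.
#' @param k_grid Candidate neighbourhood sizes.
#' @param n_folds Patient-wise folds.
#' @param seed Integer seed.
#' @return `list(k, accuracy, grid)` with the pooled CV accuracy per `k`.
#' @export
select_k <- function(features_df, subset, k_grid = 5:100, n_folds = 5,
                     seed = 1L) {
  stopifnot(length(k_grid) > 0)
  k_grid <- sort(unique(as.integer(k_grid)))
  plan <- make_patient_folds(features_df$patient_id, n_folds, seed)
  fold_of <- plan$fold[match(features_df$patient_id, plan$patient)]
  folds <- lapply(seq_len(n_folds), function(f) {
    tr <- fold_of != f
    cfc <- fit_cfc(features_df[tr, subset, drop = FALSE])
    list(train = transform_cfc(cfc, features_df[tr, subset, drop = FALSE]),
         test = transform_cfc(cfc, features_df[!tr, subset, drop = FALSE]),
         y_train = features_df$label[tr], test_idx = which(!tr))
  })
  acc <- vapply(k_grid, function(k) {
    pred <- integer(nrow(features_df))
    for (fd in folds) {
      pred[fd$test_idx] <- knn_classify(fd$train, fd$y_train, fd$test,
                                        min(k, nrow(fd$train)))
    }
    100 * mean(pred == features_df$label)
  }, numeric(1))
  best <- k_grid[which.max(acc)]  # which.max takes the first (smallest k)
  list(k = best, accuracy = max(acc),
       grid = data.frame(k = k_grid, accuracy = acc))
}

#' Exhaustive grid search over pipeline settings
#'
#' Each candidate is a list with elements `subset` (feature names) and `k`;
#' candidates are scored by [repeated_cv()] at `n_reps = 1` and the highest
#' mean accuracy wins, ties going to the earlier candidate.
#'
#' @param features_df Feature matrix (see [repeated_cv()]).
#' @param candidates List of candidate settings.
#' @param n_folds Patient-wise folds.
#' @param seed Integer seed.
#' @return `list(best, index, scores)`.
#' @export
grid_search <- function(features_df, candidates, n_folds = 5, seed = 1L) {
  if (!length(candidates)) stop("empty grid", call. = FALSE)
  scores <- vapply(candidates, function(cand) {
    repeated_cv(features_df, cand$subset, k = cand$k %||% 15,
                n_folds = n_folds, n_reps = 1, seed = seed)$mean["Ac"]
  }, numeric(1))
  idx <- which.max(scores)
  list(best = candidates[[idx]], index = idx, scores = scores)
}
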