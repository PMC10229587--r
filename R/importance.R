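# Cross-validated feature importance and recursive feature elimination.
#
# Importance is averaged over patient-disjoint folds (and repetitions of
# the fold plan), then rescaled so the largest mean equals 100. RFE removes
# the single lowest-mean feature per round, re-running the cross-validated
# importance on the surviving subset, until one feature remains; the trace
# records the elimination order, the nested subsets of every size, and a
# per-feature survival count (rounds survived: 0 for the first feature
# removed, n - 1 for the last survivor).

#' Cross-validated boosting importance
#'
#' For each repetition a fresh patient-wise fold plan is drawn; for each
#' fold a boosting model is fitted on the training patients and its
#' unscaled relevances recorded. The per-feature mean over all folds and
#' repetitions is rescaled to a maximum of 100 after averaging.
#'
#' @param X Feature matrix (columns named).
#' @param y Binary labels in {0, 1}.
#' @param patient_ids Patient identifier per row.
#' @param n_folds Folds per repetition (patient-disjoint).
#' @param n_reps Repetitions of the fold plan.
#' @param seed Master seed.
#' @param control A [boost_control()].
#' @return An `importance_table`: `data.frame(feature, relevance, sd, raw)`
#'   with attributes `n_folds` and `n_reps`.
#' @export
cv_importance <- function(X, y, patient_ids, n_folds = 5, n_reps = 30,
                          seed = 1L, control = boost_control()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  patients <- unique(patient_ids)
  if (length(patients) < n_folds) {
    stop("need at least ", n_folds, " distinct patients", call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_reps)
  raws <- matrix(NA_real_, ncol(X), n_folds * n_reps)
  k <- 0L
  for (rep in seq_len(n_reps)) {
    plan <- make_patient_folds(patient_ids, n_folds, seeds[rep])
    fold_of <- plan$fold[match(patient_ids, plan$patient)]
    for (f in seq_len(n_folds)) {
      tr <- fold_of != f
      k <- k + 1L
      if (length(unique(y[tr])) < 2L) next  # degenerate fold: skip
      model <- fit_boosting(X[tr, , drop = FALSE], y[tr], control)
      raws[, k] <- model_relevance(model)$raw
    }
  }
  ok <- colSums(is.na(raws)) == 0
  mean_raw <- rowMeans(raws[, ok, drop = FALSE])
  sd_raw <- apply(raws[, ok, drop = FALSE], 1, sd)
  mx <- max(mean_raw)
  tab <- data.frame(feature = colnames(X),
                    relevance = if (mx > 0) 100 * mean_raw / mx else 0 * mean_raw,
                    sd = sd_raw, raw = mean_raw, stringsAsFactors = FALSE)
  structure(tab, n_folds = n_folds, n_reps = n_reps,
            class = c("importance_table", "data.frame"))
}

#' Recursive feature elimination
#'
#' @param X Feature matrix (columns named).
#' @param y Binary labels in {0, 1}.
#' @param patient_ids Patient identifier per row.
#' @param n_folds,n_reps,control Passed to [cv_importance()] each round.
#' @param seed Master seed; each round uses a derived sub-seed.
#' @return An `rfe_trace`: `elimination_order` (first-removed first),
#'   `subsets` (named by size, n down to 1, strictly nested), `tables`
#'   (per-round importance tables) and `survival`
#'   (`data.frame(feature, rounds_survived)`).
#' @export
rfe_rank <- function(X, y, patient_ids, n_folds = 5, n_reps = 1, seed = 1L,
                     control = boost_control()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  current <- colnames(X)
  n <- length(current)
  seeds <- derive_seeds(seed, n)
  order_removed <- character(0)
  subsets <- stats::setNames(vector("list", n), as.character(n:1))
  tables <- vector("list", n - 1L)
  round_i <- 0L
  while (length(current) > 1L) {
    round_i <- round_i + 1L
    subsets[[as.character(length(current))]] <- current
    tab <- cv_importance(X[, current, drop = FALSE], y, patient_ids,
                         n_folds = n_folds, n_reps = n_reps,
                         seed = seeds[round_i], control = control)
    tables[[round_i]] <- tab
    lo <- min(tab$raw)
    tied <- tab$feature[tab$raw <= lo]
    drop_f <- sort(tied)[length(tied)]  # ties: remove alphabetically-last
    order_removed <- c(order_removed, drop_f)
    current <- setdiff(current, drop_f)
  }
  subsets[["1"]] <- current
  elimination <- c(order_removed, current)
  survival <- data.frame(feature = elimination,
                         rounds_survived = seq_along(elimination) - 1L,
                         stringsAsFactors = FALSE)
  structure(list(elimination_order = elimination, subsets = subsets,
                 tables = tables, survival = survival),
            class = "rfe_trace")
}

#' @export
print.rfe_trace <- function(x, ...) {
  n <- length(x$elimination_order)
  cat(sprintf("<rfe_trace> %d features; survivors (best last): %s\n", n,
              paste(tail(x$elimination_order, min(8L, n)), collapse = ", ")))
  invisible(x)
}

#' Serialize an RFE trace to JSON
#' @param trace An `rfe_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rfe_trace <- function(trace, path) {
  jsonlite::write_json(
    list(elimination_order = trace$elimination_order,
         subsets = trace$subsets, survival = trace$survival),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
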