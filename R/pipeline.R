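# End-to-end orchestration: preprocess -> features -> RFE -> subset
# selection by cross-validated accuracy -> PCA -> KNN, plus deployment-style
# single-segment prediction and lossless JSON persistence of the trained
# model.

#' Pipeline configuration
#'
#' @param feature_cfg A [feature_config()].
#' @param boost_ctrl A [boost_control()] used inside RFE.
#' @param rfe_reps Fold-plan repetitions per RFE round.
#' @param eval_reps CV repetitions when scoring each candidate subset size.
#' @param final_reps CV repetitions for the report on the selected subset.
#' @param n_folds Patient-wise folds.
#' @param k KNN size used while scoring candidate subsets.
#' @param k_grid Grid searched for the final K on the selected subset.
#' @param accuracy_floor Acceptance floor in percent: the subset with the
#'   highest mean CV accuracy (ties toward fewer features) is selected, and
#'   a warning is raised when even the best falls below the floor.
#' @param candidate_sizes Subset sizes to score (default: all).
#' @param preprocess Apply the filter chain before feature extraction.
#' @param seed Master seed for every stochastic stage.
#' @return An `saa_config` list.
#' @export
saa_config <- function(feature_cfg = feature_config(),
                       boost_ctrl = boost_control(n_trees = 30, depth = 2),
                       rfe_reps = 1, eval_reps = 3, final_reps = 5,
                       n_folds = 5, k = 15, k_grid = seq(5, 100, by = 5),
                       accuracy_floor = 99, candidate_sizes = NULL,
                       preprocess = TRUE, seed = 1L) {
  structure(list(feature_cfg = feature_cfg, boost_ctrl = boost_ctrl,
                 rfe_reps = rfe_reps, eval_reps = eval_reps,
                 final_reps = final_reps, n_folds = n_folds, k = k,
                 k_grid = k_grid, accuracy_floor = accuracy_floor,
                 candidate_sizes = candidate_sizes, preprocess = preprocess,
                 seed = as.integer(seed)),
            class = "saa_config")
}

#' Train the full shock-advice pipeline
#'
#' Runs RFE to produce nested feature subsets, scores each candidate subset
#' size with the standardize-PCA-KNN stack under repeated patient-wise CV,
#' selects the subset (smallest size attaining the accuracy floor;
#' otherwise the highest mean accuracy), grid-searches K on the selected
#' subset, and fits the deployable model on the full training cohort.
#'
#' @param segments A list of labeled [new_segment()]s (e.g. a cohort), or a
#'   feature matrix from [extract_feature_matrix()].
#' @param config An [saa_config()].
#' @return An `saa_model` with the subset, CFC model, KNN training scores,
#'   selected K, provenance seeds and a per-size report
#'   (`data.frame` with mean and sd of Ac/Se/Sp/BER per subset size).
#' @export
train_pipeline <- function(segments, config = saa_config()) {
  features_df <- if (is.data.frame(segments)) {
    segments
  } else {
    if (config$preprocess) segments <- preprocess_segments(segments)
    extract_feature_matrix(segments, config$feature_cfg, preprocess = FALSE)
  }
  if (length(unique(features_df$patient_id)) < config$n_folds) {
    stop("need at least ", config$n_folds, " patients", call. = FALSE)
  }
  if (length(unique(features_df$label)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  feat_cols <- intersect(FEATURE_NAMES, names(features_df))
  X <- as.matrix(features_df[, feat_cols, drop = FALSE])
  seeds <- derive_seeds(config$seed, 4L)

  trace <- rfe_rank(X, features_df$label, features_df$patient_id,
                    n_folds = config$n_folds, n_reps = config$rfe_reps,
                    seed = seeds[1], control = config$boost_ctrl)

  sizes <- config$candidate_sizes %||% seq_along(feat_cols)
  report <- do.call(rbind, lapply(sizes, function(sz) {
    subset <- trace$subsets[[as.character(sz)]]
    cv <- repeated_cv(features_df, subset, k = config$k,
                      n_folds = config$n_folds, n_reps = config$eval_reps,
                      seed = seeds[2])
    data.frame(size = sz, Ac = cv$mean["Ac"], Se = cv$mean["Se"],
               Sp = cv$mean["Sp"], BER = cv$mean["BER"],
               Ac_sd = cv$sd["Ac"], Se_sd = cv$sd["Se"], Sp_sd = cv$sd["Sp"],
               BER_sd = cv$sd["BER"], row.names = NULL)
  }))
  ord <- order(-report$Ac, report$size)  # highest accuracy, then smallest
  best_size <- report$size[ord[1]]
  if (report$Ac[ord[1]] < config$accuracy_floor) {
    warning(sprintf(
      "no subset reaches the %.1f%% accuracy floor; using the best available",
      config$accuracy_floor), call. = FALSE)
  }
  subset <- trace$subsets[[as.character(best_size)]]

  ksel <- select_k(features_df, subset, k_grid = config$k_grid,
                   n_folds = config$n_folds, seed = seeds[3])
  final_cv <- repeated_cv(features_df, subset, k = ksel$k,
                          n_folds = config$n_folds,
                          n_reps = config$final_reps, seed = seeds[4])

  cfc <- fit_cfc(features_df[, subset, drop = FALSE])
  scores <- transform_cfc(cfc, features_df[, subset, drop = FALSE])
  structure(list(version = "1.0", subset = subset, cfc = cfc,
                 knn = list(scores = scores, labels = features_df$label,
                            k = ksel$k),
                 feature_cfg = config$feature_cfg,
                 preprocess = config$preprocess, fs = 250,
                 provenance = list(seed = config$seed, seeds = seeds,
                                   n_folds = config$n_folds,
                                   rfe_reps = config$rfe_reps),
                 rfe = trace, report = report, final_cv = final_cv),
            class = "saa_model")
}

#' @export
print.saa_model <- function(x, ...) {
  cat(sprintf("<saa_model> %d features (%s), K=%d\n", length(x$subset),
              paste(x$subset, collapse = ", "), x$knn$k))
  cat(sprintf("  CV on training cohort: Ac %.2f%%  Se %.2f%%  Sp %.2f%%  BER %.2f%%\n",
              x$final_cv$mean["Ac"], x$final_cv$mean["Se"],
              x$final_cv$mean["Sp"], x$final_cv$mean["BER"]))
  invisible(x)
}

#' Classify one raw 8-s ECG segment
#'
#' Deployment path: resample to the model's rate if needed, preprocess,
#' extract the model's feature subset, project into component space with
#' the stored statistics, and take the KNN vote.
#'
#' @param model An [train_pipeline()] model.
#' @param samples Raw samples covering exactly 8 s.
#' @param fs Sampling frequency of `samples`.
#' @return `0L` (non-shockable) or `1L` (shockable).
#' @export
predict_segment <- function(model, samples, fs = 250) {
  stopifnot(inherits(model, "saa_model"))
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("non-finite samples", call. = FALSE)
  }
  if (fs != model$fs) {
    n_new <- round(length(samples) * model$fs / fs)
    samples <- approx((seq_along(samples) - 1) / fs, samples,
                      xout = (seq_len(n_new) - 1) / model$fs, rule = 2)$y
  }
  expected <- round(model$fs * 8)
  if (length(samples) != expected) {
    stop(sprintf("expected %d samples (8 s at %g Hz) after resampling, got %d",
                 expected, model$fs, length(samples)), call. = FALSE)
  }
  x <- if (model$preprocess) preprocess_segment(samples, model$fs) else samples
  fv <- extract_features(x, model$feature_cfg, fs = model$fs,
                         features = model$subset)
  sc <- transform_cfc(model$cfc, matrix(fv, nrow = 1,
                                        dimnames = list(NULL, names(fv))))
  knn_classify(model$knn$scores, model$knn$labels, sc, model$knn$k)[1]
}

#' Save a trained model as JSON
#'
#' Lossless, text-only persistence: numeric payloads are written at full
#' precision and the format is version-stamped.
#'
#' @param model An `saa_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "saa_model"))
  payload <- list(
    version = model$version, subset = model$subset,
    cfc = list(feature_names = model$cfc$feature_names,
               means = as.numeric(model$cfc$means),
               sds = as.numeric(model$cfc$sds),
               loadings = model$cfc$loadings,
               eigenvalues = model$cfc$eigenvalues),
    knn = list(scores = unname(model$knn$scores),
               labels = model$knn$labels, k = model$knn$k),
    feature_cfg = unclass(model$feature_cfg),
    preprocess = model$preprocess, fs = model$fs,
    provenance = model$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON path.
#' @return An `saa_model` producing predictions identical to the saved one.
#' @export
load_model <- function(path) {
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("cannot parse model file: ",
                                         conditionMessage(e), call. = FALSE))
  if (is.null(p$version) || p$version != "1.0") {
    stop("unsupported model version: ", p$version %||% "<missing>",
         call. = FALSE)
  }
  loadings <- as.matrix(p$cfc$loadings)
  dimnames(loadings) <- list(p$cfc$feature_names,
                             paste0("C", seq_len(ncol(loadings))))
  cfc <- structure(list(feature_names = p$cfc$feature_names,
                        means = stats::setNames(p$cfc$means,
                                                p$cfc$feature_names),
                        sds = stats::setNames(p$cfc$sds,
                                              p$cfc$feature_names),
                        loadings = loadings,
                        eigenvalues = p$cfc$eigenvalues),
                   class = "cfc_model")
  fc <- do.call(feature_config, as.list(p$feature_cfg))
  structure(list(version = p$version, subset = p$subset, cfc = cfc,
                 knn = list(scores = as.matrix(p$knn$scores),
                            labels = as.integer(p$knn$labels),
                            k = as.integer(p$knn$k)),
                 feature_cfg = fc, preprocess = isTRUE(p$preprocess),
                 fs = p$fs, provenance = p$provenance,
                 rfe = NULL, report = NULL, final_cv = NULL),
            class = "saa_model")
}
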