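# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# High-SNR cohort: 20 patients x 20 segments, 30% shockable, 0.01 mV noise.
easy_cohort <- function() {
  cached("easy_cohort", generate_cohort(
    synth_cohort_spec(20, 20, shock_fraction = 0.3, noise_sd = 0.01,
                      seed = 101)))
}

easy_features <- function() {
  cached("easy_features", extract_feature_matrix(easy_cohort()))
}

# Smaller high-SNR cohort for unit-level CV tests.
small_cohort <- function() {
  cached("small_cohort", generate_cohort(
    synth_cohort_spec(10, 10, shock_fraction = 0.3, noise_sd = 0.01,
                      seed = 202)))
}

small_features <- function() {
  cached("small_features", extract_feature_matrix(small_cohort()))
}

# Exactly 50 segments per class, varied per-"patient" waveform parameters.
direction_features <- function() {
  cached("direction_features", {
    segs <- c(
      lapply(1:50, function(i) {
        s <- generate_nonshockable(heart_rate_bpm = 60 + (i %% 10) * 4,
                                   qrs_mv = 0.8 + 0.04 * (i %% 10),
                                   seed = 3000 + i)
        s$patient_id <- sprintf("n%02d", i %% 10)
        s$segment_id <- sprintf("ns%02d", i)
        s
      }),
      lapply(1:50, function(i) {
        s <- generate_shockable(kind = if (i %% 3 == 0) "VT" else "VF",
                                dominant_freq_hz = if (i %% 3 == 0) {
                                  2.8 + 0.1 * (i %% 10)
                                } else 3.8 + 0.25 * (i %% 10),
                                amplitude_mv = 1.2 + 0.05 * (i %% 10),
                                seed = 4000 + i)
        s$patient_id <- sprintf("s%02d", i %% 10)
        s$segment_id <- sprintf("sh%02d", i)
        s
      }))
    extract_feature_matrix(segs)
  })
}

# Planted-signal classification problem: `informative` shifted columns among
# `p` standard-normal features, with patient structure.
planted_problem <- function(n, p, informative, shift, n_patients, seed) {
  with_local_seed <- shockadvice:::with_local_seed
  with_local_seed(seed, {
    y <- rbinom(n, 1, 0.5)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("F%02d", seq_len(p))))
    for (j in informative) X[, j] <- X[, j] + shift * y
    list(X = X, y = y,
         patient_ids = rep_len(sprintf("p%02d", seq_len(n_patients)), n))
  })
}
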