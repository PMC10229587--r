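# The 31-feature bank: temporal, spectral and complexity discriminators of
# shockable (VF/VT) versus non-shockable rhythm, each the scalar output of a
# classical single-feature VF detector ("threshold algorithm"). The feature
# set and naming follow the VF-detection literature; every tunable is frozen
# in `feature_config()` so a trained model can reproduce its inputs exactly.
#
# Conventions for degenerate input: an all-zero segment yields the fixed,
# finite vector documented at each feature (never NaN). Features are
# computed on the preprocessed segment; no per-feature output scaling is
# applied (standardization happens later, in the PCA stage).

#' Canonical feature names, in fixed column order
#' @export
FEATURE_NAMES <- c("MAva", "bCP", "TCSC", "TCin", "MEal", "SEal",
                   "Count1", "Count2", "Count3", "CFre", "A1", "A2",
                   "PSan", "CPow", "Y_Li", "bWT", "bW", "VFLM", "HTra",
                   "CCal", "PSre", "ACal", "FCal", "Kurt", "CMea", "DEnt",
                   "SEnt", "Ener", "REnt", "FEnt", "WEnt")

#' Feature extraction configuration
#'
#' Defaults: TCSC/TCin/FCal relative threshold 0.2 of the (sub)window peak,
#' TCSC sub-window 3 s; sample/fuzzy entropy with embedding `m = 2` and
#' tolerance `r = 0.2 * SD`; dispersion entropy with 6 classes and `m = 2`;
#' Renyi order 2 (spectral); phase-space grid 40 x 40 with a 0.5 s delay;
#' wavelet entropy over 6 dyadic levels of a db4 decomposition; Mexican-hat
#' kernel of width 0.1 s for the wavelet correlation feature; spectral
#' band 0.5--30 Hz with the low/high sub-bands split at 5 and 10 Hz.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A `feature_config` list.
#' @export
feature_config <- function(...) {
  cfg <- list(
    tcsc_threshold = 0.2, tcsc_window_s = 3,
    tci_threshold = 0.2, tci_window_s = 1,
    exp_tau_std_s = 1.0, exp_tau_mod_s = 0.2,
    sampen_m = 2L, sampen_r = 0.2,
    fuzzy_m = 2L, fuzzy_r = 0.2,
    disp_m = 2L, disp_classes = 6L,
    renyi_order = 2,
    psr_delay_s = 0.5, psr_grid = 40L,
    went_levels = 6L, ywt_scale_s = 0.1,
    spec_band = c(0.5, 30), low_band = c(0.5, 5), mid_band = c(5, 10),
    cpow_halfwidth_hz = 0.5, bwt_quantiles = c(0.1, 0.9),
    fcal_threshold = 0.2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown feature_config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "feature_config")
}

# One-sided periodogram (excluding DC).
segment_spectrum <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x))^2 / n
  half <- floor(n / 2)
  freq <- (1:half) * fs / n
  list(freq = freq, power = sp[2:(half + 1L)])
}

# ---- individual feature operations ----------------------------------------

#' Sample entropy
#'
#' `-ln(A/B)` with `A`, `B` the counts of (m+1)- and m-length template
#' matches within Chebyshev tolerance `r`, self-matches excluded. When no
#' (m+1)-match exists the value is capped at `log(2B)`; when no m-match
#' exists it is capped at the log of the number of template pairs.
#'
#' @param x Numeric signal.
#' @param m Embedding dimension.
#' @param r Tolerance (absolute, same units as `x`).
#' @return Non-negative scalar.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (length(x) <= m + 1 || !is.finite(r) || r <= 0) return(0)
  sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' VF-filter leakage
#'
#' The mean half-period is estimated from the mean absolute slope
#' (`round(pi * sum|x| / sum|dx|)` samples); the signal is summed with a
#' copy shifted by that half-period, and the leakage is
#' `sum|x(t) + x(t - T/2)| / sum(|x(t)| + |x(t - T/2)|)`. Near zero for a
#' quasi-sinusoid (half-period shift cancels), high for QRS trains.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency (Hz); retained for interface symmetry.
#' @return Value in [0, 1]; 0 for a zero-energy signal.
#' @export
vf_filter_leakage <- function(x, fs = 250) {
  num <- sum(abs(x))
  den <- sum(abs(diff(x)))
  if (num <= 0 || den <= 0) return(0)
  half <- round(pi * num / den)
  half <- min(max(half, 1L), length(x) - 1L)
  a <- x[(half + 1L):length(x)]
  b <- x[1L:(length(x) - half)]
  s <- sum(abs(a) + abs(b))
  if (s <= 0) return(0)
  sum(abs(a + b)) / s
}

#' Threshold crossing sample count
#'
#' Per sliding sub-window (default 3 s, stepped by 1 s), the percentage of
#' samples whose amplitude normalized by the sub-window peak exceeds
#' `threshold_frac`; averaged over sub-windows.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency in Hz.
#' @param threshold_frac Relative threshold in (0, 1).
#' @param subwin_seconds Sub-window length in seconds.
#' @return Value in [0, 100].
#' @export
threshold_crossing_sample_count <- function(x, fs, threshold_frac = 0.2,
                                            subwin_seconds = 3) {
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  n <- length(x)
  win <- min(round(subwin_seconds * fs), n)
  step <- round(fs)
  starts <- seq(1L, max(n - win + 1L, 1L), by = step)
  vals <- vapply(starts, function(s0) {
    w <- x[s0:(s0 + win - 1L)]
    mx <- max(abs(w))
    if (mx <= 0) return(0)
    100 * mean(abs(w) / mx > threshold_frac)
  }, numeric(1))
  mean(vals)
}

#' Phase-space reconstruction box fraction
#'
#' Embeds `(x(t), x(t + delay))`, partitions the normalized plane into a
#' `grid` x `grid` box grid, and returns the fraction of visited boxes.
#' A constant signal occupies a single box (`1/grid^2`).
#'
#' @param x Numeric signal.
#' @param delay Delay in samples (>= 1).
#' @param grid Boxes per axis (>= 2).
#' @return Value in `(0, 1]`.
#' @export
phase_space_fraction <- function(x, delay = 125, grid = 40) {
  stopifnot(delay >= 1, grid >= 2)
  n <- length(x)
  if (n <= delay) return(1 / grid^2)
  a <- x[1:(n - delay)]
  b <- x[(delay + 1L):n]
  rng <- range(x)
  if (diff(rng) <= 0) return(1 / grid^2)
  bin <- function(u) pmin(floor((u - rng[1]) / diff(rng) * grid), grid - 1L)
  length(unique(bin(a) * grid + bin(b))) / grid^2
}

#' Spectral band features
#'
#' From the one-sided periodogram restricted to the configured band:
#' `CFre` spectral centroid (Hz); `A1`/`A2` power fractions of the low and
#' mid sub-bands; `PSan` first spectral moment normalized by the dominant
#' frequency; `CPow` power fraction within +-0.5 Hz of the dominant peak;
#' `bWT` inter-quantile spectral width (Hz); `bW` spectral standard
#' deviation about the centroid (Hz). All zero for a zero signal.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency in Hz.
#' @param config A [feature_config()].
#' @return Named numeric vector `(CFre, A1, A2, PSan, CPow, bWT, bW)`.
#' @export
band_features <- function(x, fs, config = feature_config()) {
  out <- c(CFre = 0, A1 = 0, A2 = 0, PSan = 0, CPow = 0, bWT = 0, bW = 0)
  sp <- segment_spectrum(x, fs)
  keep <- sp$freq >= config$spec_band[1] & sp$freq <= config$spec_band[2]
  f <- sp$freq[keep]; p <- sp$power[keep]
  tot <- sum(p)
  if (!length(f) || tot <= 0) return(out)
  pn <- p / tot
  cfre <- sum(f * pn)
  f0 <- f[which.max(p)]
  out["CFre"] <- cfre
  out["A1"] <- sum(pn[f >= config$low_band[1] & f < config$low_band[2]])
  out["A2"] <- sum(pn[f >= config$mid_band[1] & f < config$mid_band[2]])
  out["PSan"] <- sum((f / f0) * pn)
  out["CPow"] <- sum(pn[abs(f - f0) <= config$cpow_halfwidth_hz])
  cdf <- cumsum(pn)
  qlo <- f[which(cdf >= config$bwt_quantiles[1])[1]]
  qhi <- f[which(cdf >= config$bwt_quantiles[2])[1]]
  out["bWT"] <- qhi - qlo
  out["bW"] <- sqrt(sum((f - cfre)^2 * pn))
  out
}

# Crossing rate of |x| through a relative threshold, per second, computed in
# 1-s windows with the threshold re-derived from each window's peak. High
# for fast disorganized rhythms, low for sparse QRS trains.
threshold_crossing_rate <- function(x, fs, threshold_frac = 0.2,
                                    window_s = 1) {
  n <- length(x)
  win <- min(round(window_s * fs), n)
  starts <- seq(1L, max(n - win + 1L, 1L), by = win)
  total <- 0
  for (s0 in starts) {
    w <- abs(x[s0:(s0 + win - 1L)])
    mx <- max(w)
    if (mx <= 0) next
    above <- w > threshold_frac * mx
    total <- total + sum(diff(above) == 1L)
  }
  total / (length(starts) * win / fs)
}

# Exponential-envelope refresh count: a running envelope decays as
# exp(-1/(fs*tau)) per sample and is lifted to |x| whenever the signal
# touches it; the count of lift events (per segment) is returned.
exp_envelope_count <- function(x, fs, tau) {
  ax <- abs(x)
  decay <- exp(-1 / (fs * tau))
  env <- ax[1]
  cnt <- 0L
  for (i in 2:length(ax)) {
    env <- env * decay
    if (ax[i] >= env) {
      env <- ax[i]
      cnt <- cnt + 1L
    }
  }
  cnt
}

# Count1..3: percentage of samples above three amplitude tiers of the
# (band-passed) segment: 0.5 * max, the mean absolute value, 0.2 * max.
count_features <- function(x) {
  ax <- abs(x)
  mx <- max(ax)
  if (mx <= 0) return(c(Count1 = 0, Count2 = 0, Count3 = 0))
  mav <- mean(ax)
  c(Count1 = 100 * mean(ax > 0.5 * mx),
    Count2 = 100 * mean(ax > mav),
    Count3 = 100 * mean(ax > 0.2 * mx))
}

# Continuous Mexican-hat wavelet response at one scale, via convolution.
cwt_mexican_hat <- function(x, fs, scale_s) {
  half <- ceiling(4 * scale_s * fs)
  t <- (-half:half) / (scale_s * fs)
  k <- (1 - t^2) * exp(-t^2 / 2)
  k <- k / sqrt(sum(k^2))
  n <- length(x)
  xp <- c(rev(x[seq_len(min(half, n))]), x, rev(x[max(1, n - half + 1):n]))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1L):(half + n)]
}

# Wavelet-domain self-similarity deficit: 1 minus the peak normalized
# cross-correlation (lags up to 1 s) between the two halves of the
# Mexican-hat transform; small when the rhythm repeats, large when not.
ywt_feature <- function(x, fs, scale_s) {
  w <- cwt_mexican_hat(x, fs, scale_s)
  n <- length(w)
  h <- floor(n / 2)
  a <- w[1:h]; b <- w[(h + 1L):(2L * h)]
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na <= 0 || nb <= 0) return(0)
  max_lag <- min(round(fs), h - 1L)
  best <- 0
  for (lag in 0:max_lag) {
    v <- abs(sum(a[1:(h - lag)] * b[(lag + 1L):h])) /
      (sqrt(sum(a[1:(h - lag)]^2)) * sqrt(sum(b[(lag + 1L):h]^2)) + 1e-12)
    if (v > best) best <- v
  }
  1 - best
}

# Hilbert-plane box fraction: analytic signal via FFT, box counting on the
# (x, H(x)) plane.
hilbert_fraction <- function(x, grid = 40) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  hx <- Im(z)
  rng_x <- range(x); rng_h <- range(hx)
  if (diff(rng_x) <= 0 || diff(rng_h) <= 0) return(1 / grid^2)
  bx <- pmin(floor((x - rng_x[1]) / diff(rng_x) * grid), grid - 1L)
  bh <- pmin(floor((hx - rng_h[1]) / diff(rng_h) * grid), grid - 1L)
  length(unique(bx * grid + bh)) / grid^2
}

# Dispersion entropy: normal-CDF mapping to `classes` symbols, embedded
# patterns of length m, Shannon entropy normalized to [0, 1].
dispersion_entropy <- function(x, m = 2L, classes = 6L) {
  n <- length(x)
  if (n <= m || sd(x) == 0) return(0)
  u <- stats::pnorm(x, mean(x), sd(x))
  z <- pmin(pmax(ceiling(u * classes), 1L), classes)
  n_pat <- n - m + 1L
  pat <- integer(n_pat)
  for (k in seq_len(m)) {
    pat <- pat * classes + z[k:(n_pat + k - 1L)]
  }
  p <- tabulate(match(pat, unique(pat)))
  p <- p / sum(p)
  -sum(p * log(p)) / log(classes^m)
}

# Shannon entropy of relative energies over `levels` dyadic detail bands of
# a db4 pyramid decomposition (periodized).
db4_lo <- c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
            0.0328830116668852, -0.0105974017850690)

wavelet_entropy <- function(x, levels = 6L) {
  lo <- db4_lo
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  energies <- numeric(levels)
  a <- x
  for (lev in seq_len(levels)) {
    n <- length(a)
    if (n < length(lo) * 2) {
      levels <- lev - 1L
      break
    }
    ap <- c(a, a[seq_len(length(lo))])  # periodized extension
    d_full <- as.numeric(stats::filter(ap, rev(hi), sides = 1))
    a_full <- as.numeric(stats::filter(ap, rev(lo), sides = 1))
    idx <- seq(length(lo), n + length(lo) - 1L, by = 2L)
    energies[lev] <- sum(d_full[idx]^2, na.rm = TRUE)
    a <- a_full[idx]
  }
  e <- energies[seq_len(max(levels, 0L))]
  tot <- sum(e)
  if (tot <= 0) return(0)
  p <- e / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

kurtosis_excess <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

lempel_ziv_norm <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  b <- as.integer(x > median(x))
  c <- lz76_cpp(b)
  c * log2(n) / n
}

renyi_spectral <- function(x, fs, order = 2, band = c(0.5, 30)) {
  sp <- segment_spectrum(x, fs)
  keep <- sp$freq >= band[1] & sp$freq <= band[2]
  p <- sp$power[keep]
  tot <- sum(p)
  if (tot <= 0) return(0)
  p <- p[p > 0] / tot
  if (order == 1) return(-sum(p * log(p)))
  log(sum(p^order)) / (1 - order)
}

# Embedded trajectory length in the delay plane, in mV (the "area swept"
# by the (x(t), x(t+delay)) trajectory).
area_calculation <- function(x, delay = 125) {
  n <- length(x)
  if (n <= delay + 1L) return(0)
  a <- x[1:(n - delay)]
  b <- x[(delay + 1L):n]
  sum(sqrt(diff(a)^2 + diff(b)^2))
}

# Transition rate (per second) of the binarized signal |x| > frac * max|x|.
frequency_calculation <- function(x, fs, frac = 0.2) {
  mx <- max(abs(x))
  if (mx <= 0) return(0)
  b <- as.integer(abs(x) > frac * mx)
  sum(abs(diff(b))) / (length(x) / fs)
}

# Mean over 1-s windows of the sample variance, normalized by the squared
# global peak (a windowed dispersion measure).
covariance_calculation <- function(x, fs) {
  mx <- max(abs(x))
  if (mx <= 0) return(0)
  n <- length(x)
  win <- min(round(fs), n)
  starts <- seq(1L, max(n - win + 1L, 1L), by = win)
  mean(vapply(starts, function(s0) {
    var(x[s0:(s0 + win - 1L)])
  }, numeric(1))) / mx^2
}

# ---- registry --------------------------------------------------------------

#' Extract the 31-dimensional feature vector from a segment
#'
#' A pure function of `(segment, config)`: all values are finite for any
#' finite input, including the all-zero segment.
#'
#' @param segment An [new_segment()] object or numeric vector (preprocessed).
#' @param config A [feature_config()].
#' @param fs Sampling frequency when `segment` is numeric.
#' @param features Optional subset of [FEATURE_NAMES] to compute.
#' @return Named numeric vector in canonical order.
#' @export
extract_features <- function(segment, config = feature_config(), fs = NULL,
                             features = NULL) {
  if (inherits(segment, "ecg_segment")) {
    x <- segment$samples
    fs <- segment$fs
  } else {
    x <- as.numeric(segment)
    if (is.null(fs)) stop("`fs` is required for a bare numeric segment",
                          call. = FALSE)
  }
  want <- features %||% FEATURE_NAMES
  bad <- setdiff(want, FEATURE_NAMES)
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  sdx <- sd(x)
  out <- stats::setNames(numeric(length(want)), want)
  need <- function(nm) nm %in% want
  if (any(c("CFre", "A1", "A2", "PSan", "CPow", "bWT", "bW") %in% want)) {
    bf <- band_features(x, fs, config)
    for (nm in intersect(names(bf), want)) out[nm] <- bf[nm]
  }
  if (need("MAva")) out["MAva"] <- mean(abs(x))
  if (need("bCP")) out["bCP"] <- mean(abs(diff(x))) / (mean(abs(x)) + 1e-12)
  if (need("TCSC")) {
    out["TCSC"] <- threshold_crossing_sample_count(x, fs,
                                                   config$tcsc_threshold,
                                                   config$tcsc_window_s)
  }
  if (need("TCin")) {
    out["TCin"] <- threshold_crossing_rate(x, fs, config$tci_threshold,
                                           config$tci_window_s)
  }
  if (need("MEal")) out["MEal"] <- exp_envelope_count(x, fs,
                                                      config$exp_tau_mod_s)
  if (need("SEal")) out["SEal"] <- exp_envelope_count(x, fs,
                                                      config$exp_tau_std_s)
  if (any(c("Count1", "Count2", "Count3") %in% want)) {
    cf <- count_features(x)
    for (nm in intersect(names(cf), want)) out[nm] <- cf[nm]
  }
  if (need("Y_Li")) out["Y_Li"] <- ywt_feature(x, fs, config$ywt_scale_s)
  if (need("VFLM")) out["VFLM"] <- vf_filter_leakage(x, fs)
  if (need("HTra")) out["HTra"] <- hilbert_fraction(x, config$psr_grid)
  if (need("CCal")) out["CCal"] <- covariance_calculation(x, fs)
  if (need("PSre")) {
    out["PSre"] <- phase_space_fraction(x, round(config$psr_delay_s * fs),
                                        config$psr_grid)
  }
  if (need("ACal")) out["ACal"] <- area_calculation(x,
                                                    round(config$psr_delay_s * fs))
  if (need("FCal")) out["FCal"] <- frequency_calculation(x, fs,
                                                         config$fcal_threshold)
  if (need("Kurt")) out["Kurt"] <- kurtosis_excess(x)
  if (need("CMea")) out["CMea"] <- lempel_ziv_norm(x)
  if (need("DEnt")) out["DEnt"] <- dispersion_entropy(x, config$disp_m,
                                                      config$disp_classes)
  if (need("SEnt")) {
    out["SEnt"] <- sample_entropy(x, config$sampen_m, config$sampen_r * sdx)
  }
  if (need("Ener")) out["Ener"] <- mean(x^2)
  if (need("REnt")) out["REnt"] <- renyi_spectral(x, fs, config$renyi_order,
                                                  config$spec_band)
  if (need("FEnt")) {
    out["FEnt"] <- if (sdx > 0) {
      fuzzyen_cpp(x, as.integer(config$fuzzy_m), config$fuzzy_r * sdx)
    } else 0
  }
  if (need("WEnt")) out["WEnt"] <- wavelet_entropy(x, config$went_levels)
  out[!is.finite(out)] <- 0
  out[want]
}

#' Build the feature matrix of a segment list
#'
#' @param segments List of [new_segment()] objects (already preprocessed,
#'   or set `preprocess = TRUE`).
#' @param config A [feature_config()].
#' @param preprocess Apply [preprocess_segment()] first.
#' @return `data.frame` with `segment_id`, `patient_id`, `label` and the 31
#'   feature columns in canonical order.
#' @export
extract_feature_matrix <- function(segments, config = feature_config(),
                                   preprocess = TRUE) {
  rows <- lapply(segments, function(s) {
    if (preprocess) s <- preprocess_segment(s)
    c(extract_features(s, config))
  })
  fm <- as.data.frame(do.call(rbind, rows))
  data.frame(segment_id = vapply(segments, function(s) s$segment_id,
                                 character(1)),
             patient_id = cohort_patients(segments),
             label = cohort_labels(segments),
             fm, stringsAsFactors = FALSE)
}
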