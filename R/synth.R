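# Synthetic single-channel ECG cohorts with patient structure.
#
# Two rhythm families are emulated at the level needed to exercise the
# detection pipeline:
#   * non-shockable: a periodic train of narrow biphasic QRS-like pulses
#     (Gaussian first derivatives, ~100 ms support) on a near-zero baseline
#     with Gaussian noise and slow (< 0.5 Hz) baseline wander;
#   * shockable: a quasi-sinusoidal, disorganized waveform whose spectral
#     content stays below 10 Hz -- VF as an amplitude- and frequency-
#     modulated sinusoid with a drifting harmonic, VT as a near-monomorphic
#     fast sinusoid-like waveform.
# Amplitudes are in millivolts, time in seconds.

#' Construct an ECG segment object
#'
#' @param samples Numeric vector of samples in millivolts.
#' @param fs Sampling frequency in Hz.
#' @param label 0 (non-shockable) or 1 (shockable).
#' @param patient_id Patient/record identifier.
#' @param segment_id Optional segment identifier.
#' @param flags Character vector of quality flags (e.g. exclusion reasons).
#' @param meta Optional list of generator or annotation metadata.
#' @return An object of class `ecg_segment`.
#' @export
new_segment <- function(samples, fs, label, patient_id = "p1",
                        segment_id = NA_character_, flags = character(),
                        meta = list()) {
  stopifnot(is.numeric(samples), length(samples) > 0L)
  structure(
    list(samples = as.numeric(samples), fs = fs, label = as.integer(label),
         patient_id = as.character(patient_id),
         segment_id = as.character(segment_id), flags = flags, meta = meta),
    class = "ecg_segment"
  )
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment> %d samples @ %g Hz, label=%d, patient=%s\n",
              length(x$samples), x$fs, x$label, x$patient_id))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Gaussian first-derivative pulse, peak-normalized to `peak_mv`.
qrs_pulse <- function(fs, peak_mv, sigma = 0.015) {
  half <- ceiling(3.5 * sigma * fs)
  t <- (-half:half) / fs
  g <- -t / sigma^2 * exp(-t^2 / (2 * sigma^2))
  g / max(abs(g)) * peak_mv
}

#' Generate a non-shockable (QRS-train) ECG segment
#'
#' A periodic train of narrow biphasic QRS-like pulses close to the
#' isoelectric line, plus Gaussian noise and optional slow baseline wander.
#'
#' @param fs Sampling frequency in Hz.
#' @param duration Segment length in seconds.
#' @param heart_rate_bpm Heart rate, 40--140 beats per minute.
#' @param qrs_mv QRS peak amplitude in mV.
#' @param noise_sd Gaussian noise standard deviation in mV.
#' @param wander_mv Baseline-wander amplitude in mV (frequency < 0.5 Hz).
#' @param seed Optional integer seed (same seed, identical samples).
#' @return An [new_segment()] object with `label = 0`.
#' @export
generate_nonshockable <- function(fs = 250, duration = 8, heart_rate_bpm = 75,
                                  qrs_mv = 1, noise_sd = 0.05,
                                  wander_mv = 0.05, seed = NULL) {
  stop_if_not_scalar_pos(fs, "fs")
  stop_if_not_scalar_pos(duration, "duration")
  if (heart_rate_bpm < 40 || heart_rate_bpm > 140) {
    stop("`heart_rate_bpm` must lie in [40, 140]", call. = FALSE)
  }
  n <- round(fs * duration)
  with_local_seed(seed, {
    x <- numeric(n)
    rate_hz <- heart_rate_bpm / 60
    n_beats <- floor(rate_hz * duration)
    pulse <- qrs_pulse(fs, qrs_mv)
    half <- (length(pulse) - 1L) / 2L
    if (n_beats >= 1) {
      centers <- round(((seq_len(n_beats) - 0.5) / rate_hz) * fs) + 1L
      for (c0 in centers) {
        lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
        x[lo:hi] <- x[lo:hi] + pulse[(lo - c0 + half + 1L):(hi - c0 + half + 1L)]
      }
    }
    if (wander_mv > 0) {
      fw <- runif(1, 0.15, 0.4)
      x <- x + wander_mv * sin(2 * pi * fw * (seq_len(n) - 1) / fs +
                                 runif(1, 0, 2 * pi))
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    new_segment(x, fs, 0L, meta = list(kind = "NSR",
                                       heart_rate_bpm = heart_rate_bpm))
  })
}

# Mean-reverting (AR(1)) random walk reflected into [lo, hi].
reflected_ar1 <- function(n, center, phi, step_sd, lo, hi) {
  v <- numeric(n)
  v[1] <- center
  for (i in seq_len(n - 1L)) {
    nxt <- center + phi * (v[i] - center) + rnorm(1, 0, step_sd)
    if (nxt > hi) nxt <- 2 * hi - nxt
    if (nxt < lo) nxt <- 2 * lo - nxt
    v[i + 1L] <- min(max(nxt, lo), hi)
  }
  v
}

#' Generate a shockable (VF/VT) ECG segment
#'
#' VF: an amplitude- and frequency-modulated quasi-sinusoid whose dominant
#' frequency performs a mean-reverting random walk within +-1.5 Hz per 1-s
#' block, with a drifting second harmonic and no QRS morphology. VT: a
#' near-monomorphic fast sinusoid-like waveform at a fixed rate.
#'
#' @param fs Sampling frequency in Hz.
#' @param duration Segment length in seconds.
#' @param kind `"VF"` or `"VT"`.
#' @param dominant_freq_hz Dominant frequency, in (0, 10] Hz.
#' @param amplitude_mv Peak-to-peak amplitude of the noise-free waveform, mV.
#' @param noise_sd Gaussian noise standard deviation in mV.
#' @param seed Optional integer seed.
#' @return An [new_segment()] object with `label = 1`.
#' @export
generate_shockable <- function(fs = 250, duration = 8, kind = c("VF", "VT"),
                               dominant_freq_hz = 5, amplitude_mv = 1.5,
                               noise_sd = 0.05, seed = NULL) {
  stop_if_not_scalar_pos(fs, "fs")
  stop_if_not_scalar_pos(duration, "duration")
  kind <- match.arg(kind)
  if (dominant_freq_hz <= 0 || dominant_freq_hz > 10) {
    stop("`dominant_freq_hz` must lie in (0, 10] (shockable bandwidth)",
         call. = FALSE)
  }
  n <- round(fs * duration)
  tt <- (seq_len(n) - 1) / fs
  with_local_seed(seed, {
    if (kind == "VF") {
      nb <- max(2L, ceiling(duration))
      f0 <- dominant_freq_hz
      fb <- reflected_ar1(nb, f0, phi = 0.55, step_sd = 0.45,
                          lo = max(0.5, f0 - 1.5), hi = min(10, f0 + 1.5))
      ab <- reflected_ar1(nb, 1, phi = 0.55, step_sd = 0.12, lo = 0.7, hi = 1.3)
      hb <- reflected_ar1(nb, 0.35, phi = 0.5, step_sd = 0.1, lo = 0.1, hi = 0.6)
      pb <- cumsum(c(runif(1, 0, 2 * pi), rnorm(nb - 1L, 0, 0.8)))
      blk_t <- (seq_len(nb) - 0.5) / nb * duration
      f_inst <- approx(blk_t, fb, xout = tt, rule = 2)$y
      a_inst <- approx(blk_t, ab, xout = tt, rule = 2)$y
      h_inst <- approx(blk_t, hb, xout = tt, rule = 2)$y
      p_inst <- approx(blk_t, pb, xout = tt, rule = 2)$y
      phase <- 2 * pi * cumsum(f_inst) / fs
      x <- a_inst * sin(phase) + h_inst * a_inst * sin(2 * phase + p_inst)
      # enforce the 0-10 Hz shockable bandwidth by construction
      lp <- signal::butter(4, 10 / (fs / 2), type = "low")
      x <- as.numeric(signal::filtfilt(lp, x))
    } else {
      skew <- runif(1, 0.3, 0.5)
      phase <- 2 * pi * dominant_freq_hz * tt
      x <- sin(phase) + skew * sin(2 * phase + 1) +
        0.05 * sin(2 * pi * 0.3 * tt)
    }
    ptp <- diff(range(x))
    if (ptp > 0) x <- x / ptp * amplitude_mv
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    new_segment(x, fs, 1L,
                meta = list(kind = kind, dominant_freq_hz = dominant_freq_hz,
                            rate_bpm = dominant_freq_hz * 60))
  })
}

#' Specification for a synthetic cohort
#'
#' The defaults describe the study conditions the cohort emulates: 8-s
#' segments at 250 Hz, a shockable prevalence of about 18 per cent, and a
#' moderate broadband noise level of 0.05 mV.
#'
#' @param n_patients Number of patients.
#' @param segments_per_patient Segments generated per patient.
#' @param shock_fraction Probability that a segment is shockable, in [0, 1].
#' @param fs Sampling frequency in Hz.
#' @param duration Segment length in seconds.
#' @param noise_sd Gaussian noise standard deviation in mV.
#' @param seed Master seed; the same seed yields a byte-identical cohort.
#' @return A `synth_cohort_spec` list.
#' @export
synth_cohort_spec <- function(n_patients, segments_per_patient,
                              shock_fraction = 0.18, fs = 250, duration = 8,
                              noise_sd = 0.05, seed = 1L) {
  stop_if_not_scalar_pos(fs, "fs")
  stop_if_not_scalar_pos(duration, "duration")
  if (shock_fraction < 0 || shock_fraction > 1) {
    stop("`shock_fraction` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_patients >= 1, segments_per_patient >= 1)
  structure(list(n_patients = as.integer(n_patients),
                 segments_per_patient = as.integer(segments_per_patient),
                 shock_fraction = shock_fraction, fs = fs, duration = duration,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_cohort_spec")
}

#' Generate a labeled synthetic cohort
#'
#' Per-patient waveform parameters (heart rate, VF dominant frequency,
#' amplitudes, VT rate) are drawn once per patient, so that patient-wise
#' cross-validation on the cohort is meaningful. Segment labels are
#' Bernoulli draws at `shock_fraction`; shockable segments are VF with
#' probability 0.7 and VT otherwise.
#'
#' @param spec A [synth_cohort_spec()].
#' @return An object of class `ecg_cohort`: a list of `ecg_segment`s with
#'   the spec attached as an attribute.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  if (spec$n_patients < 5L) {
    warning("fewer than 5 patients: patient-wise fivefold CV is not possible",
            call. = FALSE)
  }
  segs <- with_local_seed(spec$seed, {
    out <- vector("list", spec$n_patients * spec$segments_per_patient)
    k <- 0L
    for (p in seq_len(spec$n_patients)) {
      pid <- sprintf("p%03d", p)
      hr <- runif(1, 60, 100)
      f_vf <- runif(1, 3.5, 6.5)
      f_vt <- runif(1, 2.6, 4.2)   # 156--252 bpm, above the slow-VT cut
      amp_sh <- runif(1, 1.2, 1.8)
      qrs <- runif(1, 0.8, 1.2)
      labels <- rbinom(spec$segments_per_patient, 1L, spec$shock_fraction)
      kinds <- ifelse(runif(spec$segments_per_patient) < 0.7, "VF", "VT")
      for (s in seq_len(spec$segments_per_patient)) {
        sd_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        seg <- if (labels[s] == 1L) {
          generate_shockable(spec$fs, spec$duration, kinds[s],
                             dominant_freq_hz = if (kinds[s] == "VF") f_vf else f_vt,
                             amplitude_mv = amp_sh, noise_sd = spec$noise_sd,
                             seed = sd_seed)
        } else {
          generate_nonshockable(spec$fs, spec$duration, heart_rate_bpm = hr,
                                qrs_mv = qrs, noise_sd = spec$noise_sd,
                                seed = sd_seed)
        }
        k <- k + 1L
        seg$patient_id <- pid
        seg$segment_id <- sprintf("%s_s%03d", pid, s)
        out[[k]] <- seg
      }
    }
    out
  })
  structure(segs, class = "ecg_cohort", spec = spec)
}

#' @export
print.ecg_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<ecg_cohort> %d segments, %d patients, %d shockable\n",
              length(x), length(unique(cohort_patients(x))), sum(lab)))
  invisible(x)
}

#' Segment labels of a cohort or segment list
#' @param cohort A list of `ecg_segment`s.
#' @return Integer vector of 0/1 labels.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort, function(s) s$label, integer(1))
}

#' Patient identifiers of a cohort or segment list
#' @param cohort A list of `ecg_segment`s.
#' @return Character vector of patient IDs.
#' @export
cohort_patients <- function(cohort) {
  vapply(cohort, function(s) s$patient_id, character(1))
}

#' Write a cohort as a long-format CSV
#'
#' Columns: `segment_id`, `patient_id`, `label`, `sample_idx`, `mv`.
#'
#' @param cohort A list of `ecg_segment`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  dfs <- lapply(cohort, function(s) {
    data.frame(segment_id = s$segment_id, patient_id = s$patient_id,
               label = s$label, sample_idx = seq_along(s$samples) - 1L,
               mv = s$samples)
  })
  write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param path CSV path.
#' @param fs Sampling frequency of the stored segments.
#' @return An `ecg_cohort`-like list of segments.
#' @export
read_cohort_csv <- function(path, fs = 250) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$segment_id)
  segs <- lapply(ids, function(id) {
    d <- df[df$segment_id == id, ]
    d <- d[order(d$sample_idx), ]
    new_segment(d$mv, fs, d$label[1], d$patient_id[1], segment_id = id)
  })
  structure(segs, class = "ecg_cohort")
}
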