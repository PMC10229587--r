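# Segmentation, exclusion rules, and the preprocessing filter chain.
#
# Records are cut into non-overlapping 8-s windows (half-open, 0-based,
# trailing remainder dropped). A window is labeled shockable iff the rhythm
# covering the majority of the window is VF, VT or ventricular flutter;
# windows spanning more than one rhythm are flagged as transition rhythms
# and excluded downstream. The exclusion stage then drops noise, asystole
# (annotated, or detected from near-zero amplitude), transition windows,
# slow VT (< 150 bpm) and low-amplitude VF (peak-to-peak < 200 uV).
# Preprocessing applies, in order: a centred 5-point moving average, a
# first-order 1 Hz Butterworth high-pass and a second-order 30 Hz
# Butterworth low-pass, both IIR stages run forward-backward (zero phase).

SHOCKABLE_RHYTHMS <- c("VF", "VT", "VFL")
NOISE_RHYTHMS <- c("NOISE", "NOIS", "~")
ASYSTOLE_RHYTHMS <- c("ASYS", "ASYSTOLE")

#' Cut a record into non-overlapping fixed-length segments
#'
#' @param record An [new_record()] object.
#' @param seg_seconds Window length in seconds.
#' @return A list of [new_segment()] objects (empty, with a warning, if the
#'   record is shorter than one window).
#' @export
segment_record <- function(record, seg_seconds = 8) {
  stopifnot(inherits(record, "ecg_record"))
  win <- round(record$fs * seg_seconds)
  n_seg <- floor(length(record$samples) / win)
  if (n_seg == 0L) {
    warning("record shorter than one window: no segments", call. = FALSE)
    return(list())
  }
  ann <- record$annotations
  lapply(seq_len(n_seg), function(k) {
    lo <- (k - 1L) * win  # 0-based half-open [lo, lo + win)
    x <- record$samples[(lo + 1L):(lo + win)]
    lab <- 0L
    flags <- character()
    meta <- list()
    if (nrow(ann)) {
      spans <- rhythm_cover(ann, lo, lo + win, length(record$samples))
      dom <- spans$rhythm[which.max(spans$len)]
      lab <- as.integer(toupper(dom) %in% SHOCKABLE_RHYTHMS)
      meta$rhythm <- dom
      if (nrow(spans) > 1L) flags <- c(flags, "transition")
      if (any(toupper(spans$rhythm) %in% NOISE_RHYTHMS)) {
        flags <- c(flags, "noise")
      }
      if (any(toupper(spans$rhythm) %in% ASYSTOLE_RHYTHMS)) {
        flags <- c(flags, "asystole")
      }
    }
    new_segment(x, record$fs, lab, record$record_id,
                segment_id = sprintf("%s_w%04d", record$record_id, k),
                flags = flags, meta = meta)
  })
}

# Rhythm spans overlapping window [lo, hi) with their overlap lengths.
rhythm_cover <- function(ann, lo, hi, n_total) {
  onset <- ann$onset
  ends <- c(onset[-1L], n_total)
  keep <- ends > lo & onset < hi
  if (!any(keep)) {
    return(data.frame(rhythm = "unknown", len = hi - lo,
                      stringsAsFactors = FALSE))
  }
  data.frame(rhythm = ann$rhythm[keep],
             len = pmin(ends[keep], hi) - pmax(onset[keep], lo),
             stringsAsFactors = FALSE)
}

dominant_freq_hz <- function(x, fs, band = c(0.5, 10)) {
  sp <- segment_spectrum(x, fs)
  keep <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(keep) || sum(sp$power[keep]) <= 0) return(0)
  sp$freq[keep][which.max(sp$power[keep])]
}

#' Apply the segment exclusion rules
#'
#' Drops, with per-reason counts: annotation-flagged noise; asystole
#' (annotated, or any segment whose peak-to-peak amplitude is below
#' `asystole_ptp_mv`); rhythm-transition windows; VT slower than 150 bpm
#' (rate from annotation metadata when present, otherwise the dominant
#' frequency times 60); and VF with peak-to-peak amplitude under 200 uV.
#'
#' @param segments List of [new_segment()] objects.
#' @param vf_min_ptp_mv Minimum VF peak-to-peak amplitude in mV.
#' @param vt_min_bpm Minimum VT rate in beats per minute.
#' @param asystole_ptp_mv Peak-to-peak amplitude below which a segment is
#'   treated as asystole.
#' @return `list(kept, excluded, report)`; `report` is a named count per
#'   exclusion reason, which sums to `length(segments) - length(kept)`.
#' @export
apply_exclusions <- function(segments, vf_min_ptp_mv = 0.2, vt_min_bpm = 150,
                             asystole_ptp_mv = 0.05) {
  reasons <- vapply(segments, function(s) {
    ptp <- diff(range(s$samples))
    if ("noise" %in% s$flags) return("noise")
    if ("asystole" %in% s$flags || ptp < asystole_ptp_mv) return("asystole")
    if ("transition" %in% s$flags) return("transition")
    rhythm <- toupper(s$meta$rhythm %||% if (s$label == 1L) "VF" else "N")
    kind <- toupper(s$meta$kind %||% rhythm)
    if (s$label == 1L && kind == "VT") {
      rate <- s$meta$rate_bpm %||% (dominant_freq_hz(s$samples, s$fs) * 60)
      if (rate < vt_min_bpm) return("slow VT")
    }
    if (s$label == 1L && kind != "VT" && ptp < vf_min_ptp_mv) {
      return("low-amplitude VF")
    }
    ""
  }, character(1))
  kept <- segments[reasons == ""]
  excluded <- segments[reasons != ""]
  for (i in seq_along(excluded)) {
    excluded[[i]]$flags <- union(excluded[[i]]$flags,
                                 reasons[reasons != ""][i])
  }
  report <- table(factor(reasons[reasons != ""],
                         levels = c("noise", "asystole", "transition",
                                    "slow VT", "low-amplitude VF")))
  list(kept = kept, excluded = excluded,
       report = as.list(as.integer(report)) |>
         stats::setNames(names(report)))
}

# Centred length-5 moving average with reflection padding at the edges.
moving_average5 <- function(x) {
  n <- length(x)
  xp <- c(x[2:1], x, x[n:(n - 1L)])
  as.numeric(stats::filter(xp, rep(1 / 5, 5), sides = 2))[3:(n + 2L)]
}

#' Preprocess a segment
#'
#' Three stages in order: centred 5-point moving average (reflection-padded),
#' first-order 1 Hz Butterworth high-pass, second-order 30 Hz Butterworth
#' low-pass; both IIR stages are applied forward-backward for zero phase.
#' Length-preserving and deterministic (but not idempotent: a second pass
#' smooths and attenuates further).
#'
#' @param segment An [new_segment()] object or a bare numeric vector.
#' @param fs Sampling frequency, required when `segment` is numeric.
#' @return Same type as the input, with filtered samples.
#' @export
preprocess_segment <- function(segment, fs = NULL) {
  if (inherits(segment, "ecg_segment")) {
    x <- segment$samples
    fs <- segment$fs
  } else {
    x <- as.numeric(segment)
    if (is.null(fs)) stop("`fs` is required for a bare numeric segment",
                          call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("segment contains NA or non-finite samples", call. = FALSE)
  }
  y <- moving_average5(x)
  # odd-reflection padding suppresses the start/end transients of the
  # zero-phase IIR stages
  n <- length(y)
  pad <- min(n - 1L, round(3 * fs))
  yp <- c(2 * y[1] - y[(pad + 1L):2L], y,
          2 * y[n] - y[(n - 1L):(n - pad)])
  hp <- signal::butter(1, 1 / (fs / 2), type = "high")
  yp <- signal::filtfilt(hp, yp)
  lp <- signal::butter(2, 30 / (fs / 2), type = "low")
  yp <- as.numeric(signal::filtfilt(lp, yp))
  y <- yp[(pad + 1L):(pad + n)]
  if (inherits(segment, "ecg_segment")) {
    segment$samples <- y
    segment
  } else {
    y
  }
}

#' Preprocess every segment of a cohort or list
#' @param segments List of [new_segment()] objects.
#' @return The list with filtered samples.
#' @export
preprocess_segments <- function(segments) {
  out <- lapply(segments, preprocess_segment)
  class(out) <- class(segments)
  out
}

#' Record-level (wise-patient) train/validation split
#'
#' @param records List of records (or any objects carrying `record_id`), or
#'   a character vector of record IDs.
#' @param train_fraction Fraction assigned to training; the training count
#'   is `round(train_fraction * n)`.
#' @param seed Integer seed for the shuffle.
#' @return `list(train, validation)` with disjoint contents.
#' @export
split_train_validation <- function(records, train_fraction = 0.7, seed = 1L) {
  n <- length(records)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  idx <- with_local_seed(seed, sample.int(n))
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  list(train = records[sort(idx[seq_len(n_train)])],
       validation = records[sort(idx[(n_train + 1L):n])])
}
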