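# Record ingestion and export.
#
# WFDB support is a minimal native implementation of the pieces the
# pipeline needs: format-16 signal files (.dat, little-endian int16 with
# gain/baseline from the .hea header) and MIT-format annotation files
# (.atr) carrying rhythm-change annotations as aux strings such as "(VF".
# CSV records are a one-sample-per-row table with an optional JSON sidecar
# (<base>.meta.json) for the sampling frequency and an optional annotation
# sidecar (<base>.ann.csv with columns onset, rhythm).

#' Construct an ECG record
#'
#' @param samples Numeric mV series (single channel).
#' @param fs Sampling frequency in Hz.
#' @param record_id Record identifier (doubles as the patient ID).
#' @param annotations `data.frame(onset, rhythm)`: 0-based sample onsets of
#'   rhythm spans; each span extends to the next onset or the record end.
#' @return An object of class `ecg_record`.
#' @export
new_record <- function(samples, fs, record_id,
                       annotations = data.frame(onset = integer(),
                                                rhythm = character())) {
  if (length(samples) == 0L) stop("empty record: zero-length signal",
                                  call. = FALSE)
  ann <- annotations[order(annotations$onset), , drop = FALSE]
  if (nrow(ann) && (min(ann$onset) < 0 || max(ann$onset) >= length(samples))) {
    stop("annotation onsets must lie within the record", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 record_id = as.character(record_id), annotations = ann),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz, %d rhythm annotations\n",
              x$record_id, length(x$samples), x$fs, nrow(x$annotations)))
  invisible(x)
}

# ---- WFDB ------------------------------------------------------------------

#' Write a record as WFDB (.hea/.dat and optional .atr)
#'
#' Signals are stored in format 16 with a fixed gain of 200 adu/mV.
#'
#' @param record An [new_record()] object.
#' @param dir Output directory.
#' @param gain adu per millivolt.
#' @return The record base path, invisibly.
#' @export
write_wfdb <- function(record, dir, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  base <- file.path(dir, record$record_id)
  n <- length(record$samples)
  adu <- as.integer(round(record$samples * gain))
  adu <- pmax(pmin(adu, 32767L), -32768L)
  hea <- c(sprintf("%s 1 %g %d", record$record_id, record$fs, n),
           sprintf("%s.dat 16 %d 16 0 %d 0 0 ECG", record$record_id, gain,
                   adu[1]))
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(adu, con, size = 2L, endian = "little")
  close(con)
  if (nrow(record$annotations)) {
    write_wfdb_annotations(record$annotations, paste0(base, ".atr"))
  }
  invisible(base)
}

# MIT annotation format: 2-byte words, code = word >> 10, time = word & 0x3ff
# (delta-coded). Code 59 (SKIP) carries a 4-byte absolute jump, code 63 (AUX)
# carries an aux-string byte count. Rhythm changes use code 28 (RHYTHM) with
# an aux string like "(VF".
write_wfdb_annotations <- function(ann, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0L
  word <- function(code, t10) as.integer(bitwOr(bitwShiftL(code, 10), t10))
  for (i in seq_len(nrow(ann))) {
    dt <- as.integer(ann$onset[i]) - prev
    prev <- as.integer(ann$onset[i])
    if (dt > 1023L) {
      writeBin(word(59L, 0L), con, size = 2L, endian = "little")
      # 4-byte interval: high 16 bits first, then low 16 (PC-11 order)
      writeBin(as.integer(bitwShiftR(dt, 16)), con, size = 2L,
               endian = "little")
      writeBin(as.integer(bitwAnd(dt, 0xFFFFL)), con, size = 2L,
               endian = "little")
      dt <- 0L
    }
    writeBin(word(28L, dt), con, size = 2L, endian = "little")
    aux <- charToRaw(paste0("(", ann$rhythm[i]))
    writeBin(word(63L, length(aux)), con, size = 2L, endian = "little")
    writeBin(aux, con)
    if (length(aux) %% 2L == 1L) writeBin(as.raw(0L), con)
  }
  writeBin(0L, con, size = 2L, endian = "little")  # EOF word
  invisible(path)
}

read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  i <- 1L
  t_abs <- 0L
  onsets <- integer(); rhythms <- character()
  pending_rhythm <- FALSE
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  while (i + 1L <= length(raw)) {
    w <- u16(i); i <- i + 2L
    code <- bitwShiftR(w, 10)
    t10 <- bitwAnd(w, 1023L)
    if (w == 0L) break
    if (code == 59L) {
      hi <- u16(i); lo <- u16(i + 2L); i <- i + 4L
      t_abs <- t_abs + bitwShiftL(hi, 16) + lo
    } else if (code == 63L) {
      nb <- t10
      aux <- rawToChar(raw[i:(i + nb - 1L)])
      i <- i + nb + (nb %% 2L)
      if (pending_rhythm) {
        rhythms[length(rhythms)] <- sub("^\\(", "", aux)
        pending_rhythm <- FALSE
      }
    } else if (code %in% 60:62) {
      # NUM/SUB/CHN modifiers: no payload beyond the word itself
    } else {
      t_abs <- t_abs + t10
      if (code == 28L) {
        onsets <- c(onsets, t_abs)
        rhythms <- c(rhythms, "")
        pending_rhythm <- TRUE
      }
    }
  }
  data.frame(onset = onsets, rhythm = rhythms, stringsAsFactors = FALSE)
}

read_wfdb <- function(base) {
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) stop("cannot read ", hea_path, call. = FALSE)
  hea <- readLines(hea_path)
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  record_id <- top[1]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  sig <- strsplit(trimws(hea[2]), "\\s+")[[1]]  # first channel only
  fmt <- sub("\\+.*$", "", sig[2])
  if (fmt != "16") stop("only WFDB format 16 is supported", call. = FALSE)
  gain <- as.numeric(sub("\\(.*$", "", sig[3]))
  if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", sig[3])) {
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", sig[3]))
  } else 0
  dat_path <- file.path(dirname(base), strsplit(sig[1], "\\s+")[[1]][1])
  adu <- readBin(dat_path, "integer", n = nsamp * nsig, size = 2L,
                 endian = "little")
  if (nsig > 1L) adu <- adu[seq(1L, length(adu), by = nsig)]
  samples <- (adu - baseline) / gain
  atr_path <- paste0(base, ".atr")
  ann <- if (file.exists(atr_path)) read_wfdb_annotations(atr_path) else
    data.frame(onset = integer(), rhythm = character())
  new_record(samples, fs, record_id, ann)
}

# ---- CSV -------------------------------------------------------------------

read_csv_record <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  base <- sub("\\.csv$", "", path)
  meta_path <- paste0(base, ".meta.json")
  if (is.null(fs)) {
    if (file.exists(meta_path)) {
      fs <- jsonlite::read_json(meta_path)$fs
    } else if ("t" %in% names(df) && nrow(df) > 1L) {
      fs <- 1 / median(diff(df$t))
    } else {
      stop("sampling frequency unknown: supply `fs` or a .meta.json sidecar",
           call. = FALSE)
    }
  }
  mv_col <- intersect(c("mv", "mV", "amplitude"), names(df))[1]
  if (is.na(mv_col)) mv_col <- names(df)[ncol(df)]
  ann_path <- paste0(base, ".ann.csv")
  ann <- if (file.exists(ann_path)) {
    read.csv(ann_path, stringsAsFactors = FALSE)
  } else {
    data.frame(onset = integer(), rhythm = character())
  }
  new_record(df[[mv_col]], fs, basename(base), ann)
}

#' Read an ECG record from WFDB or CSV
#'
#' Multi-channel WFDB records are reduced to their first channel. Records
#' sampled at a rate other than 250 Hz are resampled to 250 Hz by linear
#' interpolation (the pipeline's passband of 1--30 Hz sits far below the
#' Nyquist frequency of every supported source).
#'
#' @param path For WFDB, the record base path (no extension); for CSV, the
#'   .csv file path.
#' @param format `"wfdb"` or `"csv"`.
#' @param fs Sampling frequency override for CSV records lacking metadata.
#' @param target_fs Sampling frequency records are normalized to.
#' @return An [new_record()] object at `target_fs`.
#' @export
read_record <- function(path, format = c("wfdb", "csv"), fs = NULL,
                        target_fs = 250) {
  format <- match.arg(format)
  rec <- switch(format, wfdb = read_wfdb(path), csv = read_csv_record(path, fs))
  resample_record(rec, target_fs)
}

resample_record <- function(record, target_fs) {
  if (record$fs == target_fs) return(record)
  n_old <- length(record$samples)
  n_new <- round(n_old * target_fs / record$fs)
  t_old <- (seq_len(n_old) - 1) / record$fs
  t_new <- (seq_len(n_new) - 1) / target_fs
  samples <- approx(t_old, record$samples, xout = t_new, rule = 2)$y
  ann <- record$annotations
  if (nrow(ann)) ann$onset <- round(ann$onset * target_fs / record$fs)
  new_record(samples, target_fs, record$record_id, ann)
}
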