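make_annotated_record <- function(minutes, fs = 250, rhythm = "N",
                                  id = "rec") {
  n <- round(minutes * 60 * fs)
  x <- sin(2 * pi * 5 * (seq_len(n) - 1) / fs)
  new_record(x, fs, id, data.frame(onset = 0L, rhythm = rhythm))
}

test_that("segmentation yields floor(length / window) segments", {
  expect_length(segment_record(make_annotated_record(8)), 60L)
  expect_length(segment_record(make_annotated_record(35)), 262L)
  short <- new_record(rnorm(7 * 250), 250, "short")
  expect_warning(segs <- segment_record(short), "shorter")
  expect_length(segs, 0L)
})

test_that("segmentation partitions the record without overlap", {
  rec <- make_annotated_record(2)
  segs <- segment_record(rec)
  tiled <- unlist(lapply(segs, function(s) s$samples))
  expect_identical(tiled, rec$samples[seq_along(tiled)])
  expect_true(all(vapply(segs, function(s) length(s$samples), integer(1)) ==
                    2000L))
})

test_that("window labels follow the covering rhythm annotation", {
  n <- 250 * 24
  x <- rnorm(n, 0, 0.1)
  ann <- data.frame(onset = c(0L, 2000L, 4500L),
                    rhythm = c("N", "VF", "N"))
  segs <- segment_record(new_record(x, 250, "r", ann))
  expect_identical(cohort_labels(segs)[1:3], c(0L, 1L, 0L))
  # window 2 is pure VF; window 3 straddles a transition
  expect_false("transition" %in% segs[[2]]$flags)
  expect_true("transition" %in% segs[[3]]$flags)
})

test_that("exclusion rules drop the annotated and amplitude-based cases", {
  keepers <- list(generate_nonshockable(seed = 1),
                  generate_shockable(kind = "VF", seed = 2))
  low_vf <- generate_shockable(kind = "VF", amplitude_mv = 0.15,
                               noise_sd = 0, seed = 3)  # ptp 150 uV
  slow_vt <- generate_shockable(kind = "VT", dominant_freq_hz = 2,
                                seed = 4)               # 120 bpm
  noisy <- generate_nonshockable(seed = 5)
  noisy$flags <- "noise"
  flat <- new_segment(rnorm(2000, 0, 0.005), 250, 0)    # near-zero amplitude
  trans <- generate_nonshockable(seed = 6)
  trans$flags <- "transition"
  res <- apply_exclusions(c(keepers, list(low_vf, slow_vt, noisy, flat,
                                          trans)))
  expect_length(res$kept, 2L)
  expect_equal(res$report[["low-amplitude VF"]], 1L)
  expect_equal(res$report[["slow VT"]], 1L)
  expect_equal(res$report[["noise"]], 1L)
  expect_equal(res$report[["asystole"]], 1L)
  expect_equal(res$report[["transition"]], 1L)
  expect_equal(sum(unlist(res$report)), 7L - length(res$kept))
})

test_that("preprocessing kills DC and preserves the passband", {
  fs <- 250
  t <- (0:1999) / fs
  dc <- preprocess_segment(rep(1, 2000), fs)
  expect_lt(max(abs(dc)), 0.01)
  # closed-form oracle for the IIR stages (applied forward-backward):
  # 2nd-order Butterworth low-pass |H|^2 and 1st-order high-pass |H|^2
  butter2_lp <- function(f, fc) 1 / sqrt(1 + (f / fc)^4)
  butter1_hp <- function(f, fc) (f / fc) / sqrt(1 + (f / fc)^2)
  gain_at <- function(f_hz) {
    y <- preprocess_segment(sin(2 * pi * f_hz * t), fs)
    core <- 500:1500  # avoid filter edge transients
    max(abs(y[core]))
  }
  g5 <- gain_at(5)
  expect_gt(g5, 0.8)
  expect_lt(g5, 1.2)
  oracle5 <- (butter2_lp(5, 30) * butter1_hp(5, 1))^2
  expect_equal(g5, oracle5, tolerance = 0.15)
  # 50 Hz: attenuated at least as much as the Butterworth stage alone
  g50 <- gain_at(50)
  oracle50_db <- -20 * log10(butter2_lp(50, 30)^2)  # about 18.8 dB
  expect_gt(-20 * log10(g50 / g5), min(oracle50_db, 8))
})

test_that("preprocessing is length-preserving, deterministic, non-idempotent", {
  x <- generate_shockable(seed = 9)$samples
  y1 <- preprocess_segment(x, 250)
  y2 <- preprocess_segment(x, 250)
  expect_identical(y1, y2)
  expect_length(y1, length(x))
  expect_false(isTRUE(all.equal(preprocess_segment(y1, 250), y1)))
  expect_error(preprocess_segment(c(x[-1], NA), 250), "NA")
})

test_that("train/validation split is record-disjoint with the stated sizes", {
  recs <- sprintf("rec%02d", 1:57)
  sp <- split_train_validation(recs, 0.7, seed = 4)
  expect_length(sp$train, 40L)
  expect_length(sp$validation, 17L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  sp10 <- split_train_validation(sprintf("r%d", 1:10), 0.7, seed = 4)
  expect_length(sp10$train, 7L)
  for (seed in 1:20) {
    s <- split_train_validation(recs, 0.7, seed = seed)
    expect_length(intersect(s$train, s$validation), 0L)
    expect_setequal(c(s$train, s$validation), recs)
  }
  expect_error(split_train_validation("one"), "at least 2")
})
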