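periodogram_peak_hz <- function(x, fs) {
  n <- length(x)
  P <- Mod(fft(x))^2
  f <- (0:(n - 1)) * fs / n
  keep <- seq(2L, floor(n / 2))
  f[keep][which.max(P[keep])]
}

test_that("non-shockable generator produces the requested pulse train", {
  s <- generate_nonshockable(fs = 250, duration = 8, heart_rate_bpm = 75,
                             noise_sd = 0, wander_mv = 0, seed = 1)
  expect_length(s$samples, 2000L)
  expect_identical(s$label, 0L)
  # 75 bpm over 8 s: exactly 10 detectable pulse peaks
  x <- s$samples
  peaks <- which(x > 0.5 * max(x) &
                   x >= c(-Inf, head(x, -1)) & x > c(tail(x, -1), -Inf))
  expect_equal(length(peaks), 10L)
  # baseline stays near the isoelectric line between pulses
  expect_lt(median(abs(x)), 0.05)
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(generate_nonshockable(seed = 7)$samples,
                   generate_nonshockable(seed = 7)$samples)
  expect_identical(generate_shockable(seed = 7)$samples,
                   generate_shockable(seed = 7)$samples)
  expect_false(identical(generate_shockable(seed = 7)$samples,
                         generate_shockable(seed = 8)$samples))
})

test_that("generator argument validation", {
  expect_error(generate_nonshockable(fs = 0), "fs")
  expect_error(generate_nonshockable(duration = -1), "duration")
  expect_error(generate_nonshockable(heart_rate_bpm = 20), "heart_rate_bpm")
  expect_error(generate_shockable(dominant_freq_hz = 12), "bandwidth")
  expect_error(generate_shockable(dominant_freq_hz = 0), "bandwidth")
})

test_that("VF dominant frequency lands near the requested value", {
  for (seed in 1:10) {
    x <- generate_shockable(kind = "VF", dominant_freq_hz = 5,
                            seed = seed)$samples
    expect_lt(abs(periodogram_peak_hz(x, 250) - 5), 1)
  }
})

test_that("shockable amplitude is controllable down to the exclusion zone", {
  s <- generate_shockable(amplitude_mv = 0.1, noise_sd = 0, seed = 3)
  expect_lt(diff(range(s$samples)), 0.2)
  expect_identical(s$label, 1L)
})

test_that("VF spectra are band-limited and sit below the QRS-train centroid", {
  centroid <- function(x, fs) {
    n <- length(x)
    P <- Mod(fft(x))^2
    f <- (0:(n - 1)) * fs / n
    keep <- f > 0 & f <= fs / 2
    sum(f[keep] * P[keep]) / sum(P[keep])
  }
  vf_cent <- qrs_cent <- numeric(10)
  for (seed in 1:10) {
    xv <- generate_shockable(kind = "VF", seed = seed)$samples
    xq <- generate_nonshockable(seed = seed)$samples
    n <- length(xv)
    P <- Mod(fft(xv))^2
    f <- (0:(n - 1)) * 250 / n
    keep <- f > 0 & f <= 125
    expect_lt(sum(P[keep & f > 10]) / sum(P[keep]), 0.05)
    vf_cent[seed] <- centroid(xv, 250)
    qrs_cent[seed] <- centroid(xq, 250)
  }
  expect_lt(mean(vf_cent), mean(qrs_cent))
})

test_that("cohorts have the requested shape and patient structure", {
  coh <- generate_cohort(synth_cohort_spec(10, 20, shock_fraction = 0.3,
                                           seed = 5))
  expect_length(coh, 200L)
  expect_length(unique(cohort_patients(coh)), 10L)
  all0 <- generate_cohort(synth_cohort_spec(6, 5, shock_fraction = 0,
                                            seed = 5))
  expect_true(all(cohort_labels(all0) == 0L))
  expect_warning(generate_cohort(synth_cohort_spec(3, 5, seed = 5)),
                 "fivefold")
})

test_that("cohort generation is byte-identical under one seed", {
  spec <- synth_cohort_spec(6, 8, seed = 99)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
})

test_that("cohort class mix follows the binomial at scale", {
  # 6320 segments at the 1135/6320 prevalence: the shockable count must sit
  # inside the 99% binomial interval around 1135
  p <- 1135 / 6320
  coh <- generate_cohort(synth_cohort_spec(316, 20, shock_fraction = p,
                                           seed = 17))
  n_shock <- sum(cohort_labels(coh))
  half <- 2.576 * sqrt(6320 * p * (1 - p))
  expect_gt(n_shock, 1135 - half)
  expect_lt(n_shock, 1135 + half)
})

test_that("cohort CSV round-trips", {
  coh <- generate_cohort(synth_cohort_spec(5, 2, seed = 23))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_length(back, length(coh))
  expect_equal(back[[3]]$samples, coh[[3]]$samples, tolerance = 1e-12)
  expect_identical(cohort_labels(back), cohort_labels(coh))
})
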