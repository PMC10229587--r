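fs <- 250
tt <- (0:1999) / fs

test_that("every segment yields 31 finite named features in fixed order", {
  cfg <- feature_config()
  for (seed in 1:3) {
    seg <- if (seed %% 2) generate_shockable(seed = seed) else
      generate_nonshockable(seed = seed)
    fv <- extract_features(preprocess_segment(seg), cfg)
    expect_identical(names(fv), FEATURE_NAMES)
    expect_true(all(is.finite(fv)))
  }
  # all-zero segment: defined conventions, never NaN
  fz <- extract_features(rep(0, 2000), fs = fs)
  expect_true(all(is.finite(fz)))
  expect_equal(unname(fz["MAva"]), 0)
  expect_equal(unname(fz["Ener"]), 0)
  expect_equal(unname(fz["PSre"]), 1 / 1600)
})

test_that("extract_features is a pure function of segment and config", {
  x <- generate_shockable(seed = 5)$samples
  expect_identical(extract_features(x, fs = fs), extract_features(x, fs = fs))
})

test_that("sample entropy matches a brute-force template-count oracle", {
  sampen_oracle <- function(x, m, r) {
    N <- length(x) - m
    A <- B <- 0L
    for (i in 1:(N - 1)) {
      for (j in (i + 1):N) {
        dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
        if (dm <= r) {
          B <- B + 1L
          if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
        }
      }
    }
    -log(A / B)
  }
  set.seed(42)
  x <- rnorm(80)
  r <- 0.2 * sd(x)
  expect_equal(sample_entropy(x, 2, r), sampen_oracle(x, 2, r),
               tolerance = 1e-12)
  x2 <- sin(2 * pi * 5 * (0:199) / 250) + rnorm(200, 0, 0.01)
  r2 <- 0.2 * sd(x2)
  expect_equal(sample_entropy(x2, 2, r2), sampen_oracle(x2, 2, r2),
               tolerance = 1e-12)
})

test_that("sample entropy behaves at its limits", {
  expect_equal(sample_entropy(rep(1, 500)), 0)
  # strict periodicity with tolerance above the noise floor: only same-phase
  # templates match and every m-match extends, so the count ratio is 1
  per <- rep(c(0, 1, 3, 2, 5), 400)
  expect_lt(sample_entropy(per, 2, 0.2 * sd(per)), 1e-10)
  # i.i.d. Gaussian at n = 2000, m = 2, r = 0.2 SD: known band
  for (seed in 1:5) {
    set.seed(seed)
    g <- rnorm(2000)
    v <- sample_entropy(g, 2, 0.2 * sd(g))
    expect_gt(v, 1.5)
    expect_lt(v, 2.8)
  }
  # noise is less regular than a tone
  set.seed(1)
  noise <- rnorm(2000)
  tone <- sin(2 * pi * 5 * tt)
  expect_gt(sample_entropy(noise, 2, 0.2 * sd(noise)),
            sample_entropy(tone, 2, 0.2 * sd(tone)))
})

test_that("VF-filter leakage separates sinusoids from QRS trains", {
  sine <- sin(2 * pi * 5 * tt)
  expect_lt(vf_filter_leakage(sine, fs), 0.1)
  qrs <- generate_nonshockable(noise_sd = 0, wander_mv = 0, seed = 1)$samples
  expect_lt(vf_filter_leakage(sine, fs), vf_filter_leakage(qrs, fs))
  expect_equal(vf_filter_leakage(rep(0, 2000), fs), 0)
})

test_that("TCSC spans its range and orders the rhythm classes", {
  square <- rep(c(1, -1), each = 25, length.out = 2000)
  expect_gt(threshold_crossing_sample_count(square, fs), 99)
  expect_equal(threshold_crossing_sample_count(rep(0, 2000), fs), 0)
  vf <- preprocess_segment(generate_shockable(seed = 2))$samples
  qrs <- preprocess_segment(generate_nonshockable(seed = 2))$samples
  expect_gt(threshold_crossing_sample_count(vf, fs),
            threshold_crossing_sample_count(qrs, fs))
})

test_that("phase-space fraction counts visited boxes", {
  expect_equal(phase_space_fraction(rep(3, 2000), 125, 40), 1 / 1600)
  sine <- sin(2 * pi * 5 * tt)
  set.seed(1)
  noise <- rnorm(2000)
  f_sine <- phase_space_fraction(sine, 125, 40)
  f_noise <- phase_space_fraction(noise, 125, 40)
  expect_lt(f_sine, f_noise)
  for (v in c(f_sine, f_noise)) {
    expect_gt(v, 0)
    expect_lte(v, 1)
  }
})

test_that("spectral band features track the periodogram", {
  sine <- sin(2 * pi * 5 * tt)
  bf <- band_features(sine, fs)
  expect_equal(unname(bf["CFre"]), 5, tolerance = 0.05)
  set.seed(2)
  noise <- rnorm(2000)
  expect_gt(band_features(sine, fs)["CPow"], band_features(noise, fs)["CPow"])
  qrs <- preprocess_segment(generate_nonshockable(seed = 3))$samples
  expect_gt(band_features(qrs, fs)["bW"], band_features(sine, fs)["bW"])
  expect_true(all(band_features(rep(0, 2000), fs) == 0))
})

test_that("kurtosis, energy and complexity conventions hold", {
  set.seed(8)
  ks <- replicate(100, shockadvice:::kurtosis_excess(rnorm(2000)))
  expect_lt(abs(mean(ks)), 0.25)
  expect_true(all(abs(ks) < 1))
  expect_equal(unname(extract_features(rep(0, 2000), fs = fs,
                                       features = "Ener")), 0)
  expect_lt(shockadvice:::lempel_ziv_norm(rep(1, 2000)), 0.05)
})

test_that("amplitude scaling affects only the amplitude-carrying features", {
  x <- preprocess_segment(generate_shockable(seed = 11))$samples
  f1 <- extract_features(x, fs = fs)
  f3 <- extract_features(3 * x, fs = fs)
  expect_equal(unname(f3["MAva"]), unname(3 * f1["MAva"]), tolerance = 1e-9)
  expect_equal(unname(f3["Ener"]), unname(9 * f1["Ener"]), tolerance = 1e-9)
  for (nm in c("TCSC", "SEnt", "FEnt", "DEnt", "CMea", "PSre", "CFre",
               "VFLM", "Count1", "Count2", "Count3")) {
    expect_equal(unname(f3[nm]), unname(f1[nm]), tolerance = 1e-6,
                 label = nm)
  }
})

test_that("feature matrices carry ids, labels and canonical columns", {
  fm <- small_features()
  expect_identical(names(fm), c("segment_id", "patient_id", "label",
                                FEATURE_NAMES))
  expect_equal(nrow(fm), 100L)
  expect_true(all(vapply(fm[FEATURE_NAMES], function(col) all(is.finite(col)),
                         logical(1))))
})
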