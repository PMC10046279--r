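test_that("bandpass keeps in-band tones and crushes sub-band drift", {
  fs <- 250
  t <- (0:4999) / fs
  inband <- sin(2 * pi * 4 * t)
  lowdrift <- sin(2 * pi * 0.05 * t)
  rms <- function(x) sqrt(mean(x^2))
  atten_db <- function(x) -20 * log10(rms(bandpass(x, fs_hz = fs)) / rms(x))
  expect_lt(atten_db(inband), 3)
  expect_gt(atten_db(lowdrift), 20)
  expect_identical(bandpass(rep(0, 5000), fs_hz = fs), rep(0, 5000))
  expect_error(bandpass(inband, low_hz = 10, high_hz = 5, fs_hz = fs),
               "invalid band")
  expect_error(bandpass(inband, low_hz = 0.5, high_hz = 200, fs_hz = fs),
               "invalid band")
})

test_that("peak detection finds beats, handles flat input, and sees troughs on negation", {
  seg <- generate_segment(clean_spec(seed = 2, hr = 60))
  pk <- detect_peaks(seg)
  expect_true(abs(length(pk$indices) - 20) <= 1)
  expect_true(all(diff(pk$indices) > 0))
  expect_identical(pk$amplitudes, seg$values[pk$indices])
  flat <- ecg_segment(rep(0, 5000), 250L)
  expect_length(detect_peaks(flat)$indices, 0)
  # negated input: detected maxima sit where the original has minima
  neg <- seg; neg$values <- -seg$values
  pkn <- detect_peaks(neg)
  expect_gt(length(pkn$indices), 0)
  expect_true(mean(seg$values[pkn$indices]) <= mean(seg$values))
})

test_that("subsegment splitting follows the window arithmetic", {
  seg <- generate_segment(clean_spec(seed = 1))
  s4 <- subsegments(seg, 4)
  expect_length(s4, 5)
  expect_true(all(lengths(s4) == 1000))
  expect_identical(unlist(s4, use.names = FALSE), seg$values)
  s20 <- subsegments(seg, 20)
  expect_length(s20, 1)
  expect_length(s20[[1]], 5000)
  expect_error(subsegments(seg, 3), "divide")
})

test_that("correlation, shape, DTW and spectral primitives match brute-force oracles", {
  set.seed(31)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(ecgsqc:::autocorr_seq(x, 4), oracle_autocorr(x, 4),
               tolerance = 1e-12)
  expect_equal(ecgsqc:::crosscorr_seq(x, y, 3), oracle_crosscorr(x, y, 3),
               tolerance = 1e-12)
  expect_equal(e1071::skewness(x, type = 1), oracle_skew(x),
               tolerance = 1e-12)
  expect_equal(e1071::kurtosis(x, type = 1), oracle_kurt(x),
               tolerance = 1e-12)
  expect_equal(dtw_distance(x, y), oracle_dtw(x, y), tolerance = 1e-12)
  z <- rnorm(64)
  expect_equal(hurst_rs(z), oracle_hurst(z), tolerance = 1e-10)
  # STFT magnitudes of one frame against an explicit DFT
  fr <- rnorm(100)
  w <- 0.5 * (1 - cos(2 * pi * (0:99) / 100))
  st <- stft_mag(fr, fs_hz = 250, window = 100, overlap = 50)
  expect_equal(as.numeric(st$mag[, 1]), oracle_dft_mag(fr, w)[1:51],
               tolerance = 1e-9)
  p <- runif(20)
  expect_equal(spectral_entropy(p), oracle_entropy(p), tolerance = 1e-12)
})

test_that("hurst exponent separates white noise from an integrated walk", {
  set.seed(7)
  wn <- rnorm(1000)
  expect_lt(abs(hurst_rs(wn) - 0.5), 0.15)
  expect_gt(hurst_rs(cumsum(wn)), 0.8)
})

test_that("a linear ramp has constant slope features", {
  fs <- 250L
  a <- 0.3
  seg <- ecg_segment(a * (0:4999) / fs, fs)
  f <- extract_features(seg)
  expect_equal(unname(f["mean(slopes)"]), a / fs, tolerance = 1e-12)
  expect_equal(unname(f["stddev(slopes)"]), 0, tolerance = 1e-12)
})

test_that("feature vectors are fixed-width, named and deterministic", {
  seg <- generate_segment(segment_spec(noise_sigma_mv = 0.15, seed = 6))
  f1 <- extract_features(seg)
  f2 <- extract_features(seg)
  expect_length(f1, 43)
  expect_identical(names(f1), feature_names())
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_true(all(is.finite(f1)))
})

test_that("degenerate input hits the sentinel policy instead of NA/NaN", {
  flat <- ecg_segment(rep(0.5, 5000), 250L)
  f <- extract_features(flat)
  expect_true(all(is.finite(f)))
  valid <- attr(f, "valid")
  expect_false(valid[["mean(autocorr)"]])
  expect_false(valid[["max(zscore(peakamplitude))"]])
  expect_identical(unname(f["mean(autocorr)"]), 0)
  # subsegment shape statistics are defined (all zero spread)
  expect_identical(unname(f["stddev(skew)"]), 0)
})

test_that("negated-signal features equal plain features of the flipped waveform", {
  seg <- generate_segment(segment_spec(noise_sigma_mv = 0.12,
                                       wander_amplitude_mv = 0.4, seed = 13))
  f <- extract_features(seg)
  neg <- seg; neg$values <- -seg$values
  fneg <- extract_features(neg)
  pairs <- list(
    c("max(peakamplitude_neg)", "max(peakamplitude)"),
    c("max(zscore(peakamplitude_neg))", "max(zscore(peakamplitude))"),
    c("mean(autocorr_neg)", "mean(autocorr)"),
    c("stddev(autocorr_neg)", "stddev(autocorr)"),
    c("mean(crosscorr_neg)", "mean(crosscorr)"),
    c("mean(skew_neg)", "mean(skew)"),
    c("stddev(skew_neg)", "stddev(skew)"),
    c("mean(kurtosis_neg)", "mean(kurtosis)"),
    c("mean(he_neg)", "mean(he)"),
    c("mean(dtw_neg)", "mean(dtw)"),
    c("mean(maxpower_neg)", "mean(maxpower)"))
  for (p in pairs) {
    expect_equal(unname(f[p[1]]), unname(fneg[p[2]]), tolerance = 1e-9,
                 label = p[1])
  }
})

test_that("clean periodic segments cross-correlate more strongly than noisy twins", {
  clean <- generate_segment(clean_spec(seed = 21, hr = 75))
  noisy <- generate_segment(segment_spec(heart_rate_bpm = 75,
                                         noise_sigma_mv = 0.6, seed = 21))
  fc <- extract_features(clean)
  fn <- extract_features(noisy)
  expect_gt(fc["mean(crosscorr)"], fn["mean(crosscorr)"])
})

test_that("slope variability separates acceptable from unacceptable segments", {
  d <- generate_dataset(c(50, 50, 0), seed = 17)
  labs <- segment_labels(d)
  ft <- extract_features_batch(d)
  a <- ft[labs == "acceptable", "stddev(slopes)"]
  b <- ft[labs == "unacceptable", "stddev(slopes)"]
  expect_lt(wilcox.test(a, b)$p.value, 0.01)
})

test_that("k-best selection ranks by the ANOVA F statistic", {
  set.seed(12)
  y <- rep(c("a", "b"), each = 3)
  X <- cbind(sep = c(0, 0.1, -0.1, 5, 5.2, 4.9),   # perfectly separating
             weak = rnorm(6),
             const = rep(1, 6))
  sel <- select_k_best(X, y, k = 3)
  expect_identical(sel[1], "sep")
  expect_identical(sel[3], "const")  # constant column ranked last
  expect_identical(as.character(select_k_best(X, y, k = 1)), "sep")
  # F statistics agree with stats::aov on non-degenerate columns
  scores <- attr(sel, "scores")
  expect_equal(unname(scores["sep"]), oracle_f_stat(X[, "sep"], y),
               tolerance = 1e-9)
  expect_equal(unname(scores["weak"]), oracle_f_stat(X[, "weak"], y),
               tolerance = 1e-9)
  expect_error(select_k_best(X, y, k = 0), "k must be")
  expect_error(select_k_best(X, rep("a", 6), k = 1), "2 classes")
})
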