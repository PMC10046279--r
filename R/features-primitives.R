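# Signal primitives behind the quality features: bandpass filtering,
# adaptive-threshold peak detection, correlation sequences, rescaled-range
# Hurst estimation, DTW, and short-time Fourier machinery.

#' Bandpass-filter a segment
#'
#' Zero-phase Butterworth bandpass (order 3, forward-backward) used to remove
#' very low frequencies and high-frequency noise before R-peak detection.
#' Default band is 0.5-8 Hz.
#'
#' @param seg An [ecg_segment()] or numeric vector.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param fs_hz Sampling rate; taken from the segment when given one.
#' @return Filtered signal of the same type and length as the input.
#' @export
bandpass <- function(seg, low_hz = 0.5, high_hz = 8, fs_hz = NULL) {
  is_seg <- inherits(seg, "ecg_segment")
  x <- if (is_seg) seg$values else as.numeric(seg)
  fs <- if (is_seg) seg$fs_hz else fs_hz
  if (is.null(fs)) stop("fs_hz required for plain numeric input")
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2))
    stop("invalid band: need 0 < low < high < fs/2", call. = FALSE)
  bf <- signal::butter(3, c(low_hz, high_hz) / (fs / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, x))
  if (is_seg) { seg$values <- y; seg } else y
}

# Centred moving average with edges padded by the overall mean (the padding
# convention of adaptive-threshold beat detectors).
rolling_mean <- function(x, width) {
  n <- length(x)
  width <- min(width, n)
  k <- rep(1 / width, width)
  rm <- as.numeric(stats::filter(x, k, sides = 2))
  rm[is.na(rm)] <- mean(x)
  rm
}

#' Detect R-peak candidates
#'
#' Adaptive-threshold local-maximum detection in the style of beat detectors
#' for noisy wearable data: the signal is bandpass filtered, shifted
#' nonnegative, and compared against a 0.75-s rolling mean raised by a set of
#' candidate percentages; contiguous supra-threshold regions each contribute
#' their maximum as a peak. The threshold whose inter-beat intervals give a
#' plausible heart rate (40-200 bpm) with the lowest RR variability wins.
#' Peak amplitudes are read from the **unfiltered** signal.
#'
#' @param seg An [ecg_segment()].
#' @param low_hz,high_hz Bandpass edges used before detection.
#' @return A `peak_set`: list with sorted `indices` (sample positions) and
#'   `amplitudes` (mV on the original signal). May hold fewer than 2 peaks
#'   (downstream features then apply their sentinel policy).
#' @export
detect_peaks <- function(seg, low_hz = 0.5, high_hz = 8) {
  stopifnot(inherits(seg, "ecg_segment"))
  fs <- seg$fs_hz
  filt <- bandpass(seg$values, low_hz, high_hz, fs_hz = fs)
  s <- filt - min(filt)
  base <- rolling_mean(s, width = as.integer(round(0.75 * fs)))
  lift <- mean(s)
  candidates <- list()
  for (perc in c(5, 10, 15, 20, 25, 30, 40, 50, 100, 150, 200, 300)) {
    thr <- base + perc / 100 * lift
    above <- s > thr
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values
    pk <- mapply(function(a, b) a - 1L + which.max(s[a:b]),
                 starts[keep], ends[keep])
    pk <- as.integer(pk)
    if (length(pk) < 2) {
      candidates[[length(candidates) + 1]] <-
        list(pk = pk, rrsd = Inf, bpm = NA_real_)
      next
    }
    rr <- diff(pk) / fs
    bpm <- 60 / mean(rr)
    rrsd <- sd(rr)
    if (is.na(rrsd)) rrsd <- Inf  # two peaks: a single interval has no sd
    candidates[[length(candidates) + 1]] <-
      list(pk = pk, rrsd = rrsd, bpm = bpm)
  }
  if (length(candidates) == 0)
    return(structure(list(indices = integer(0), amplitudes = numeric(0)),
                     class = "peak_set"))
  valid <- vapply(candidates, function(cd) {
    !is.na(cd$bpm) && cd$bpm >= 40 && cd$bpm <= 200
  }, logical(1))
  pool <- if (any(valid)) candidates[valid] else candidates
  best <- pool[[which.min(vapply(pool, function(cd) cd$rrsd, numeric(1)))]]
  idx <- best$pk
  structure(list(indices = idx, amplitudes = seg$values[idx]),
            class = "peak_set")
}

#' Split a segment into nonoverlapping subsegments
#'
#' The feature definitions aggregate per-subsegment statistics over five
#' contiguous nonoverlapping 4-s subsegments of the 20-s segment.
#'
#' @param seg An [ecg_segment()].
#' @param window_s Subsegment length in seconds; must divide the duration.
#' @return List of numeric vectors, in temporal order.
#' @export
subsegments <- function(seg, window_s = 4) {
  stopifnot(inherits(seg, "ecg_segment"))
  n <- length(seg$values)
  w <- window_s * seg$fs_hz
  if (abs(w - round(w)) > 1e-9 || n %% round(w) != 0)
    stop("window_s must divide the segment duration", call. = FALSE)
  w <- as.integer(round(w))
  lapply(seq_len(n %/% w), function(i) seg$values[((i - 1) * w + 1):(i * w)])
}

# Normalised autocorrelation at lags 1..lag_max; NULL when variance is 0.
autocorr_seq <- function(x, lag_max) {
  if (var(x) == 0) return(NULL)
  as.numeric(acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf)[-1]
}

# Normalised cross-correlation at lags -lag_max..lag_max; NULL if degenerate.
crosscorr_seq <- function(x, y, lag_max) {
  if (var(x) == 0 || var(y) == 0) return(NULL)
  as.numeric(stats::ccf(x, y, lag.max = lag_max, plot = FALSE)$acf)
}

#' Rescaled-range Hurst exponent
#'
#' Classical R/S estimate of long-range dependence: for a geometric ladder of
#' block sizes, the range of the cumulative mean-adjusted sums divided by the
#' block standard deviation is averaged over nonoverlapping blocks, and the
#' exponent is the slope of log(R/S) against log(block size).
#'
#' @param x Numeric vector (needs >= 16 samples and nonzero variance).
#' @return The exponent estimate, or `NA` for degenerate input.
#' @export
hurst_rs <- function(x) {
  n <- length(x)
  if (n < 16 || is.na(var(x)) || var(x) == 0) return(NA_real_)
  sizes <- unique(round(exp(seq(log(8), log(floor(n / 2)), length.out = 6))))
  rs_mean <- vapply(sizes, function(s) {
    nb <- n %/% s
    rs <- vapply(seq_len(nb), function(b) {
      xb <- x[((b - 1) * s + 1):(b * s)]
      sdb <- sd(xb)
      if (is.na(sdb) || sdb == 0) return(NA_real_)
      y <- cumsum(xb - mean(xb))
      (max(y) - min(y)) / sdb
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs_mean) & rs_mean > 0
  if (sum(ok) < 2) return(NA_real_)
  unname(coef(stats::lm.fit(cbind(1, log(sizes[ok])),
                            log(rs_mean[ok])))[2])
}

#' Dynamic-time-warping distance
#'
#' Unconstrained DTW with absolute-difference local cost and the standard
#' symmetric step pattern; returns the cumulative cost of the optimal
#' alignment path (unnormalised).
#'
#' @param a,b Numeric vectors.
#' @return The DTW distance.
#' @export
dtw_distance <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) > 0, length(b) > 0)
  dtw_dist(as.numeric(a), as.numeric(b))
}

# Periodic window functions for the STFT.
stft_window <- function(kind, n) {
  switch(kind,
         hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)),
         rect = rep(1, n),
         stop("unknown window kind: ", kind))
}

#' Short-time Fourier transform magnitudes
#'
#' Frames of `window` samples at hop `window - overlap` are tapered by a
#' periodic Hann (or rectangular) window and Fourier transformed; magnitudes
#' of the one-sided spectrum are returned as a frequency x time matrix.
#'
#' @param x Numeric vector.
#' @param fs_hz Sampling rate.
#' @param window Window length in samples (default 100).
#' @param overlap Overlap in samples (default 50, i.e. 50%).
#' @param kind `"hann"` or `"rect"`.
#' @param onesided Return only bins 0..window/2 (default); set FALSE for the
#'   full two-sided spectrum.
#' @return List with `mag` (matrix, rows = frequency bins, cols = frames),
#'   `freq_hz` and `time_s` axis vectors.
#' @export
stft_mag <- function(x, fs_hz, window = 100, overlap = 50, kind = "hann",
                     onesided = TRUE) {
  n <- length(x)
  hop <- window - overlap
  stopifnot(hop > 0, n >= window)
  starts <- seq(1, n - window + 1, by = hop)
  w <- stft_window(kind, window)
  nb <- if (onesided) window %/% 2 + 1 else window
  mag <- vapply(starts, function(s) {
    abs(fft(x[s:(s + window - 1)] * w))[seq_len(nb)]
  }, numeric(nb))
  list(mag = matrix(mag, nrow = nb),
       freq_hz = (seq_len(nb) - 1) * fs_hz / window,
       time_s = (starts - 1 + window / 2) / fs_hz)
}

#' Shannon spectral entropy
#'
#' Entropy (natural log) of a power spectrum normalised to a probability
#' distribution; `NA` when the total power is 0.
#'
#' @param power Nonnegative numeric vector of spectral power values.
#' @return Entropy in nats.
#' @export
spectral_entropy <- function(power) {
  s <- sum(power)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  p <- power / s
  p <- p[p > 0]
  -sum(p * log(p))
}

# One-sided FFT power spectrum excluding the DC bin (offset carries no
# morphology); returns max power and the frequency at which it occurs.
max_power_freq <- function(x, fs_hz) {
  n <- length(x)
  pw <- Mod(fft(x))^2
  idx <- 2:(n %/% 2 + 1)
  pw <- pw[idx]
  if (all(pw == 0)) return(c(power = NA_real_, freq = NA_real_))
  i <- which.max(pw)
  c(power = pw[i], freq = (idx[i] - 1) * fs_hz / n)
}

# Within-segment z-scores of detected peak amplitudes.
zscore <- function(a) {
  s <- sd(a)
  if (is.na(s) || s == 0) return(NULL)
  (a - mean(a)) / s
}
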