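#' Names of the 43 quality features
#'
#' The fixed registry of hand-engineered features: 1-34 are time-domain,
#' 35-43 frequency-domain. The `_neg` suffix marks features defined on the
#' negated (polarity-flipped) waveform, which matter because peak detectors
#' return peaks but not troughs and ECG polarity can flip abruptly.
#'
#' @return Character vector of length 43, in canonical order.
#' @export
feature_names <- function() c(
  "mean(slopes)", "stddev(slopes)",
  "max(zscore(peakamplitude))",
  "min(zscore(peakamplitude_neg))", "max(zscore(peakamplitude_neg))",
  "max(peakamplitude)", "max(peakamplitude_neg)",
  "stddev(mean(peakamplitude))", "stddev(max(peakamplitude))",
  "stddev(min(peakminamplitude))",
  "mean(autocorr)", "stddev(autocorr)",
  "mean(autocorr_neg)", "stddev(autocorr_neg)",
  "mean(crosscorr)", "stddev(crosscorr)",
  "mean(crosscorr_neg)", "stddev(crosscorr_neg)",
  "mean(skew)", "mean(skew_neg)", "stddev(skew)", "stddev(skew_neg)",
  "mean(kurtosis)", "mean(kurtosis_neg)",
  "stddev(kurtosis)", "stddev(kurtosis_neg)",
  "mean(he)", "stddev(he)", "mean(he_neg)", "stddev(he_neg)",
  "mean(dtw)", "stddev(dtw)", "mean(dtw_neg)", "stddev(dtw_neg)",
  "mean(maxpower)", "stddev(maxpower)",
  "mean(maxpower_neg)", "stddev(maxpower_neg)",
  "stddev(meanpowerdiff)", "stddev(meanfreqdiff)",
  "mean(abs(stft))", "std(abs(stft))", "stddev(se)")

# sd with the degenerate-input convention used throughout: NA for < 2 values.
sd_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) NA_real_ else sd(x)
}
mean_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

#' Extract the 43 quality features from one segment
#'
#' Computes the full feature vector for a preprocessed segment. Statistics
#' named `mean(f)`/`stddev(f)` aggregate per-subsegment values over the five
#' nonoverlapping 4-s subsegments; `slopes` is the first difference of the
#' full segment; autocorrelation uses lags up to 1 s; cross-correlation and
#' DTW compare the four adjacent subsegment pairs; `maxpower` is the peak of
#' the one-sided FFT power spectrum (DC excluded) per subsegment;
#' `meanpowerdiff`/`meanfreqdiff` are successive between-subsegment
#' differences of that peak's power and frequency; the STFT features use a
#' 100-sample periodic Hann window with 50% overlap.
#'
#' Negated-signal (`_neg`) variants are obtained from the sign-flipped
#' waveform. On fixed subsegments several of them coincide analytically with
#' the plain variants (autocorrelation, cross-correlation, kurtosis, Hurst,
#' DTW and FFT power are polarity-invariant, and skewness only changes sign),
#' and the implementation uses those identities; only peak-derived features
#' genuinely depend on polarity.
#'
#' Degenerate inputs (constant signal, fewer than two detected peaks, zero
#' variance) yield the sentinel value 0 for the affected features, with the
#' per-feature `valid` attribute flagging them, so the vector stays
#' fixed-width for the classifiers.
#'
#' @param seg A preprocessed [ecg_segment()] of standard 20-s length.
#' @param window_s Subsegment length in seconds (default 4).
#' @return Named numeric vector of length 43 with attributes `valid` (named
#'   logical) and `segment_id` (if the segment carries one).
#' @export
extract_features <- function(seg, window_s = 4) {
  stopifnot(inherits(seg, "ecg_segment"))
  fs <- seg$fs_hz
  x <- seg$values
  subs <- subsegments(seg, window_s = window_s)
  ns <- length(subs)
  sub_of <- function(idx) pmin(ns, (idx - 1) %/% (window_s * fs) + 1)

  out <- stats::setNames(rep(NA_real_, 43), feature_names())

  ## slopes: first difference of the full segment
  slopes <- diff(x)
  out["mean(slopes)"] <- mean(slopes)
  out["stddev(slopes)"] <- sd(slopes)

  ## peak-derived features (positive peaks and peaks of the negated signal)
  pk <- detect_peaks(seg)
  neg_seg <- seg; neg_seg$values <- -x
  pk_neg <- detect_peaks(neg_seg)
  if (length(pk$indices) >= 2) {
    z <- zscore(pk$amplitudes)
    if (!is.null(z)) out["max(zscore(peakamplitude))"] <- max(z)
    out["max(peakamplitude)"] <- max(pk$amplitudes)
    grp <- sub_of(pk$indices)
    per_mean <- tapply(pk$amplitudes, factor(grp, levels = seq_len(ns)), mean)
    per_max <- tapply(pk$amplitudes, factor(grp, levels = seq_len(ns)), max)
    out["stddev(mean(peakamplitude))"] <- sd_or_na(as.numeric(per_mean))
    out["stddev(max(peakamplitude))"] <- sd_or_na(as.numeric(per_max))
  }
  if (length(pk_neg$indices) >= 2) {
    zn <- zscore(pk_neg$amplitudes)
    if (!is.null(zn)) {
      out["min(zscore(peakamplitude_neg))"] <- min(zn)
      out["max(zscore(peakamplitude_neg))"] <- max(zn)
    }
    out["max(peakamplitude_neg)"] <- max(pk_neg$amplitudes)
    # troughs of the original signal: its value at negated-signal peaks
    trough <- x[pk_neg$indices]
    grp <- sub_of(pk_neg$indices)
    per_min <- tapply(trough, factor(grp, levels = seq_len(ns)), min)
    out["stddev(min(peakminamplitude))"] <- sd_or_na(as.numeric(per_min))
  }

  ## autocorrelation over lags 1..fs (1 s), pooled across subsegments;
  ## polarity-invariant, so the _neg values are identical
  ac <- unlist(lapply(subs, autocorr_seq, lag_max = fs))
  out["mean(autocorr)"] <- mean_or_na(ac)
  out["stddev(autocorr)"] <- sd_or_na(ac)
  out["mean(autocorr_neg)"] <- out["mean(autocorr)"]
  out["stddev(autocorr_neg)"] <- out["stddev(autocorr)"]

  ## cross-correlation of adjacent subsegment pairs (polarity-invariant)
  cc <- unlist(lapply(seq_len(ns - 1), function(i)
    crosscorr_seq(subs[[i]], subs[[i + 1]], lag_max = fs)))
  out["mean(crosscorr)"] <- mean_or_na(cc)
  out["stddev(crosscorr)"] <- sd_or_na(cc)
  out["mean(crosscorr_neg)"] <- out["mean(crosscorr)"]
  out["stddev(crosscorr_neg)"] <- out["stddev(crosscorr)"]

  ## distribution shape per subsegment; skew flips sign under negation,
  ## (excess) kurtosis does not
  sk <- vapply(subs, function(s) e1071::skewness(s, type = 1), numeric(1))
  ku <- vapply(subs, function(s) e1071::kurtosis(s, type = 1), numeric(1))
  out["mean(skew)"] <- mean_or_na(sk)
  out["stddev(skew)"] <- sd_or_na(sk)
  out["mean(skew_neg)"] <- -out["mean(skew)"]
  out["stddev(skew_neg)"] <- out["stddev(skew)"]
  out["mean(kurtosis)"] <- mean_or_na(ku)
  out["stddev(kurtosis)"] <- sd_or_na(ku)
  out["mean(kurtosis_neg)"] <- out["mean(kurtosis)"]
  out["stddev(kurtosis_neg)"] <- out["stddev(kurtosis)"]

  ## Hurst exponent per subsegment (R/S; polarity-invariant)
  he <- vapply(subs, hurst_rs, numeric(1))
  out["mean(he)"] <- mean_or_na(he)
  out["stddev(he)"] <- sd_or_na(he)
  out["mean(he_neg)"] <- out["mean(he)"]
  out["stddev(he_neg)"] <- out["stddev(he)"]

  ## DTW distances between adjacent subsegment pairs (polarity-invariant)
  dtw <- vapply(seq_len(ns - 1), function(i)
    dtw_distance(subs[[i]], subs[[i + 1]]), numeric(1))
  out["mean(dtw)"] <- mean_or_na(dtw)
  out["stddev(dtw)"] <- sd_or_na(dtw)
  out["mean(dtw_neg)"] <- out["mean(dtw)"]
  out["stddev(dtw_neg)"] <- out["stddev(dtw)"]

  ## FFT peak power / frequency per subsegment (polarity-invariant)
  mp <- vapply(subs, max_power_freq, numeric(2), fs_hz = fs)
  out["mean(maxpower)"] <- mean_or_na(mp["power", ])
  out["stddev(maxpower)"] <- sd_or_na(mp["power", ])
  out["mean(maxpower_neg)"] <- out["mean(maxpower)"]
  out["stddev(maxpower_neg)"] <- out["stddev(maxpower)"]
  out["stddev(meanpowerdiff)"] <- sd_or_na(diff(mp["power", ]))
  out["stddev(meanfreqdiff)"] <- sd_or_na(diff(mp["freq", ]))

  ## STFT magnitude statistics and spectral entropy over frames
  st <- stft_mag(x, fs, window = 100, overlap = 50, kind = "hann")
  out["mean(abs(stft))"] <- mean(st$mag)
  out["std(abs(stft))"] <- sd(as.numeric(st$mag))
  se <- apply(st$mag^2, 2, spectral_entropy)
  out["stddev(se)"] <- sd_or_na(se)

  valid <- is.finite(out)
  out[!valid] <- 0
  attr(out, "valid") <- valid
  attr(out, "segment_id") <- attr(seg, "segment_id")
  out
}

#' Extract features for a batch of segments
#'
#' @param segments Named list of [ecg_segment()]s.
#' @param window_s Subsegment length, see [extract_features()].
#' @return `data.frame` with a `segment_id` column plus the 43 feature
#'   columns (names as in [feature_names()]).
#' @export
extract_features_batch <- function(segments, window_s = 4) {
  ids <- names(segments)
  if (is.null(ids)) ids <- sprintf("seg_%05d", seq_along(segments))
  mat <- t(vapply(segments, function(s)
    as.numeric(extract_features(s, window_s = window_s)), numeric(43)))
  colnames(mat) <- feature_names()
  df <- data.frame(segment_id = ids, mat, check.names = FALSE,
                   row.names = NULL)
  df
}

#' Univariate feature selection by ANOVA F-statistic
#'
#' Ranks feature columns by the one-way between-class ANOVA F-statistic and
#' returns the names of the top `k`, the classical k-best univariate filter.
#' Constant columns have an undefined F and are ranked last.
#'
#' @param X Numeric matrix or data.frame of features (named columns).
#' @param y Class labels (>= 2 classes present).
#' @param k Number of features to keep (1 <= k <= ncol(X)).
#' @return Character vector of the `k` selected names, best first, with the
#'   F-statistics attached as the `scores` attribute.
#' @export
select_k_best <- function(X, y, k) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- droplevels(factor(y))
  g <- nlevels(y)
  if (g < 2) stop("need at least 2 classes", call. = FALSE)
  if (k <= 0 || k > ncol(X)) stop("k must be in 1..ncol(X)", call. = FALSE)
  n <- nrow(X)
  grand <- colMeans(X)
  ssb <- numeric(ncol(X)); ssw <- numeric(ncol(X))
  for (lv in levels(y)) {
    Xi <- X[y == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    ssb <- ssb + nrow(Xi) * (mi - grand)^2
    ssw <- ssw + colSums(sweep(Xi, 2, mi)^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[!is.finite(f) & ssb == 0] <- -Inf  # constant column: rank last
  ord <- order(f, decreasing = TRUE)
  sel <- colnames(X)[ord][seq_len(k)]
  structure(sel, scores = stats::setNames(f[ord], colnames(X)[ord])[seq_len(k)])
}
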