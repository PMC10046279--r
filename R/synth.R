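#' Specification of one synthetic ECG segment
#'
#' Describes a quasi-periodic QRS train plus the contamination sources seen on
#' continuously recording patient monitors: baseline wander, broadband noise,
#' powerline interference, extreme spikes (pacing-like artefacts may exceed
#' 100 mV) and blank (zero) runs from transmission gaps.
#'
#' @param heart_rate_bpm Heart rate in beats per minute (positive).
#' @param fs_hz Sampling rate in Hz (positive integer, default 250).
#' @param duration_s Segment duration in seconds (default 20).
#' @param qrs_amplitude_mv R-wave amplitude in mV.
#' @param wander_amplitude_mv Baseline-wander amplitude in mV (>= 0).
#' @param wander_freq_hz Baseline-wander frequency in Hz (>= 0).
#' @param noise_sigma_mv Standard deviation of additive Gaussian noise in mV.
#' @param powerline_amplitude_mv Mains-interference amplitude in mV.
#' @param powerline_freq_hz Mains frequency, 60 Hz by default (50 Hz in
#'   50 Hz-grid countries).
#' @param spike_count Number of abrupt spikes to inject (>= 0).
#' @param spike_amplitude_mv Spike amplitude in mV; may exceed 100 (such
#'   spikes are zeroed later by the amplitude clipper).
#' @param blank_runs List of `c(start_s, duration_s)` pairs zeroed out of the
#'   signal; must lie inside `[0, duration_s]`.
#' @param seed Integer seed; the same spec and seed always produce an
#'   identical segment.
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(heart_rate_bpm = 75, fs_hz = 250L, duration_s = 20,
                         qrs_amplitude_mv = 1, wander_amplitude_mv = 0,
                         wander_freq_hz = 0.3, noise_sigma_mv = 0,
                         powerline_amplitude_mv = 0, powerline_freq_hz = 60,
                         spike_count = 0L, spike_amplitude_mv = 3,
                         blank_runs = list(), seed = 1L) {
  if (!is.numeric(heart_rate_bpm) || heart_rate_bpm <= 0)
    stop("invalid spec: heart_rate_bpm must be positive", call. = FALSE)
  if (!is.numeric(fs_hz) || fs_hz <= 0 || fs_hz != round(fs_hz))
    stop("invalid spec: fs_hz must be a positive integer", call. = FALSE)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("invalid spec: duration_s must be positive", call. = FALSE)
  n <- fs_hz * duration_s
  if (abs(n - round(n)) > 1e-9)
    stop("invalid spec: fs_hz * duration_s must be an integer", call. = FALSE)
  stopifnot(wander_amplitude_mv >= 0, wander_freq_hz >= 0,
            noise_sigma_mv >= 0, powerline_amplitude_mv >= 0,
            spike_count >= 0)
  if (length(blank_runs) > 0) {
    ok <- vapply(blank_runs, function(r) {
      length(r) == 2 && r[1] >= 0 && r[2] >= 0 && r[1] + r[2] <= duration_s
    }, logical(1))
    if (!all(ok))
      stop("invalid spec: blank runs must lie inside [0, duration_s]",
           call. = FALSE)
  }
  structure(list(
    heart_rate_bpm = heart_rate_bpm, fs_hz = as.integer(fs_hz),
    duration_s = duration_s, qrs_amplitude_mv = qrs_amplitude_mv,
    wander_amplitude_mv = wander_amplitude_mv, wander_freq_hz = wander_freq_hz,
    noise_sigma_mv = noise_sigma_mv,
    powerline_amplitude_mv = powerline_amplitude_mv,
    powerline_freq_hz = powerline_freq_hz, spike_count = as.integer(spike_count),
    spike_amplitude_mv = spike_amplitude_mv, blank_runs = blank_runs,
    seed = as.integer(seed)
  ), class = "segment_spec")
}

#' Construct an ECG segment object
#'
#' @param values Numeric vector of amplitudes in mV.
#' @param fs_hz Sampling rate in Hz.
#' @param label Optional quality label (one of [quality_classes()]).
#' @return An object of class `ecg_segment`.
#' @export
ecg_segment <- function(values, fs_hz = 250L, label = NULL) {
  stopifnot(is.numeric(values), length(values) > 0)
  if (!is.null(label)) label <- as.character(as_quality_factor(label))
  structure(list(values = as.numeric(values), fs_hz = as.integer(fs_hz),
                 label = label),
            class = "ecg_segment")
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment> %d samples @ %d Hz (%.1f s)%s\n",
              length(x$values), x$fs_hz, length(x$values) / x$fs_hz,
              if (is.null(x$label)) "" else paste0(", label: ", x$label)))
  invisible(x)
}

#' Class-assignment thresholds for synthetic segments
#'
#' The expert judgments behind the three quality classes are emulated by a
#' construction rule on the contamination parameters: a segment is
#' *acceptable* when noise and wander are both below the low thresholds and no
#' spikes or blanks are present, *unacceptable* when noise or wander reach the
#' high thresholds (QRS complexes indistinguishable / extreme baseline sways)
#' or any spike is present, and *uncertain* otherwise. Thresholds are in mV
#' and are stand-ins calibrated against a ~1 mV QRS amplitude, not values
#' estimated from data.
#'
#' @param noise_lo,noise_hi Noise-sd bounds (mV) separating the classes.
#' @param wander_lo,wander_hi Wander-amplitude bounds (mV).
#' @return A named list of thresholds.
#' @export
label_thresholds <- function(noise_lo = 0.05, noise_hi = 0.30,
                             wander_lo = 0.20, wander_hi = 1.50) {
  stopifnot(noise_lo < noise_hi, wander_lo < wander_hi)
  list(noise_lo = noise_lo, noise_hi = noise_hi,
       wander_lo = wander_lo, wander_hi = wander_hi)
}

# Label-by-construction rule (see label_thresholds).
label_for_spec <- function(spec, thresholds = label_thresholds()) {
  th <- thresholds
  has_blanks <- length(spec$blank_runs) > 0
  if (spec$noise_sigma_mv >= th$noise_hi ||
      spec$wander_amplitude_mv >= th$wander_hi ||
      spec$spike_count > 0) {
    "unacceptable"
  } else if (spec$noise_sigma_mv <= th$noise_lo &&
             spec$wander_amplitude_mv <= th$wander_lo &&
             !has_blanks) {
    "acceptable"
  } else {
    "uncertain"
  }
}

#' Generate one labelled synthetic ECG segment
#'
#' The clean waveform is a quasi-periodic train of beats, each beat a sum of
#' Gaussian lobes (P, Q, R, S, T) centred on the beat time, with mild
#' inter-beat-interval jitter. Contaminations from the spec are then added and
#' the quality label is assigned by the construction rule of
#' [label_thresholds()].
#'
#' @param spec A [segment_spec()].
#' @param thresholds Labelling thresholds, see [label_thresholds()].
#' @return An [ecg_segment()] with a label.
#' @export
generate_segment <- function(spec, thresholds = label_thresholds()) {
  if (!inherits(spec, "segment_spec")) stop("spec must be a segment_spec")
  fs <- spec$fs_hz
  n <- as.integer(round(fs * spec$duration_s))
  withr::with_seed(spec$seed, {
    t <- (seq_len(n) - 1) / fs
    ibi <- 60 / spec$heart_rate_bpm
    # beat times with 2% RR jitter, random initial phase
    n_beats <- ceiling(spec$duration_s / ibi) + 2L
    rr <- ibi * (1 + rnorm(n_beats, 0, 0.02))
    beats <- runif(1, 0, ibi) + cumsum(c(0, rr))
    beats <- beats[beats < spec$duration_s + 0.4]
    x <- numeric(n)
    amp <- spec$qrs_amplitude_mv
    # (relative amplitude, offset s, width s) for the P, Q, R, S, T lobes
    lobes <- list(c(0.12, -0.20, 0.040), c(-0.12, -0.035, 0.009),
                  c(1.00, 0.000, 0.012), c(-0.18, 0.035, 0.009),
                  c(0.28, 0.280, 0.070))
    for (tb in beats) {
      lo <- max(1L, floor((tb - 0.6) * fs)); hi <- min(n, ceiling((tb + 0.8) * fs))
      if (lo > hi) next
      tt <- t[lo:hi]
      contrib <- 0
      for (lb in lobes)
        contrib <- contrib + amp * lb[1] * exp(-(tt - tb - lb[2])^2 / (2 * lb[3]^2))
      x[lo:hi] <- x[lo:hi] + contrib
    }
    if (spec$wander_amplitude_mv > 0 && spec$wander_freq_hz > 0)
      x <- x + spec$wander_amplitude_mv *
        sin(2 * pi * spec$wander_freq_hz * t + runif(1, 0, 2 * pi))
    if (spec$noise_sigma_mv > 0)
      x <- x + rnorm(n, 0, spec$noise_sigma_mv)
    if (spec$powerline_amplitude_mv > 0)
      x <- x + spec$powerline_amplitude_mv *
        sin(2 * pi * spec$powerline_freq_hz * t + runif(1, 0, 2 * pi))
    if (spec$spike_count > 0) {
      pos <- sample.int(n - 2L, spec$spike_count)
      sgn <- sample(c(-1, 1), spec$spike_count, replace = TRUE)
      for (i in seq_along(pos)) {
        w <- sample(1:2, 1)  # 1-2 samples wide
        idx <- pos[i]:(pos[i] + w - 1L)
        x[idx] <- x[idx] + sgn[i] * spec$spike_amplitude_mv
      }
    }
    for (r in spec$blank_runs) {
      i0 <- floor(r[1] * fs) + 1L
      i1 <- min(n, i0 + as.integer(round(r[2] * fs)) - 1L)
      if (i1 >= i0) x[i0:i1] <- 0
    }
    ecg_segment(x, fs, label_for_spec(spec, thresholds))
  })
}

# Default per-class contamination ranges for dataset generation. Each entry
# gives uniform sampling bounds; ranges leave a margin to the labelling
# thresholds so the constructed label always matches the requested class.
class_spec_ranges <- function(thresholds = label_thresholds()) {
  th <- thresholds
  list(
    acceptable = list(noise = c(0, 0.8 * th$noise_lo),
                      wander = c(0, 0.75 * th$wander_lo),
                      powerline = c(0, 0.03)),
    uncertain = list(noise = c(1.6 * th$noise_lo, 0.85 * th$noise_hi),
                     wander = c(1.5 * th$wander_lo, 0.8 * th$wander_hi),
                     powerline = c(0, 0.08)),
    unacceptable = list(noise = c(1.3 * th$noise_hi, 1),
                        wander = c(1.3 * th$wander_hi, 4),
                        spike_amp = c(2, 4.5), spike_n = c(5, 20),
                        powerline = c(0, 0.08))
  )
}

# Draw a segment_spec of the requested class inside the active RNG stream.
sample_class_spec <- function(class, ranges, thresholds, fs_hz, duration_s) {
  r <- ranges[[class]]
  runif2 <- function(b) runif(1, b[1], b[2])
  hr <- runif(1, 50, 120)
  qrs <- runif(1, 0.7, 1.5)
  noise <- 0; wander <- 0; spikes <- 0L; spike_amp <- 3
  if (class == "acceptable") {
    noise <- runif2(r$noise); wander <- runif2(r$wander)
  } else if (class == "uncertain") {
    # mildly flawed: at least one of noise / wander in the mild band
    mode <- sample(c("noise", "wander", "both"), 1)
    noise <- if (mode != "wander") runif2(r$noise) else
      runif(1, 0, 0.8 * thresholds$noise_lo)
    wander <- if (mode != "noise") runif2(r$wander) else
      runif(1, 0, 0.75 * thresholds$wander_lo)
  } else {
    # severe flaw: heavy noise, extreme sway, or spike train
    mode <- sample(c("noise", "wander", "spikes"), 1, prob = c(0.4, 0.3, 0.3))
    if (mode == "noise") noise <- runif2(r$noise)
    if (mode == "wander") wander <- runif2(r$wander)
    if (mode == "spikes") {
      spikes <- sample(r$spike_n[1]:r$spike_n[2], 1)
      spike_amp <- runif2(r$spike_amp)
      noise <- runif(1, 0, 0.8 * thresholds$noise_lo)
    }
  }
  segment_spec(heart_rate_bpm = hr, fs_hz = fs_hz, duration_s = duration_s,
               qrs_amplitude_mv = qrs, wander_amplitude_mv = wander,
               wander_freq_hz = runif(1, 0.15, 0.5), noise_sigma_mv = noise,
               powerline_amplitude_mv = runif2(r$powerline),
               spike_count = spikes, spike_amplitude_mv = spike_amp,
               seed = sample.int(2147483646L, 1))
}

#' Generate a labelled synthetic dataset
#'
#' Returns exactly the requested number of segments per class (supporting the
#' heavy class imbalance of continuous monitoring data, where ~95% of
#' segments are acceptable). Counts may be given directly or as proportions
#' with a total `n`; proportional counts are floored per class and the
#' shortfall is assigned to the last class.
#'
#' @param n_per_class Integer vector of length 3: segments for the
#'   acceptable, unacceptable and uncertain classes (in that order). Ignored
#'   when `proportions` is given.
#' @param proportions Optional numeric vector of length 3 of class
#'   proportions; requires `n`.
#' @param n Total number of segments when `proportions` is used.
#' @param thresholds Labelling thresholds, see [label_thresholds()].
#' @param ranges Per-class contamination sampling ranges; defaults depend on
#'   `thresholds`.
#' @param fs_hz,duration_s Segment geometry (250 Hz, 20 s by default).
#' @param shuffle Randomise segment order (default TRUE).
#' @param seed Integer seed controlling the whole dataset.
#' @return A list of labelled [ecg_segment()]s, named `seg_00001`, ..., with
#'   a `manifest` attribute (`data.frame` of segment_id and label).
#' @export
generate_dataset <- function(n_per_class = c(100, 10, 10), proportions = NULL,
                             n = NULL, thresholds = label_thresholds(),
                             ranges = NULL, fs_hz = 250L, duration_s = 20,
                             shuffle = TRUE, seed = 1L) {
  if (!is.null(proportions)) {
    stopifnot(length(proportions) == 3, !is.null(n))
    counts <- floor(proportions * n)
    counts[3] <- counts[3] + (n - sum(counts))
  } else {
    stopifnot(length(n_per_class) == 3)
    counts <- as.integer(n_per_class)
  }
  if (any(counts < 0)) stop("requested class counts must be >= 0")
  if (is.null(ranges)) ranges <- class_spec_ranges(thresholds)
  classes <- quality_classes()
  withr::with_seed(as.integer(seed), {
    lab_seq <- rep(classes, times = counts)
    if (shuffle) lab_seq <- sample(lab_seq)
    segs <- vector("list", length(lab_seq))
    for (i in seq_along(lab_seq)) {
      spec <- sample_class_spec(lab_seq[i], ranges, thresholds, fs_hz, duration_s)
      seg <- generate_segment(spec, thresholds)
      stopifnot(seg$label == lab_seq[i])  # ranges guarantee the class
      segs[[i]] <- seg
    }
  })
  names(segs) <- sprintf("seg_%05d", seq_along(segs))
  attr(segs, "manifest") <- data.frame(
    segment_id = names(segs),
    label = vapply(segs, function(s) s$label, character(1)),
    row.names = NULL)
  segs
}

#' Extract the label vector of a dataset
#'
#' @param segments A list of labelled [ecg_segment()]s.
#' @return Factor of labels over [quality_classes()].
#' @export
segment_labels <- function(segments) {
  as_quality_factor(vapply(segments, function(s) {
    if (is.null(s$label)) NA_character_ else s$label
  }, character(1)))
}
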