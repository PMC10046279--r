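#' Blank-run exclusion decision
#'
#' A 20-s segment is excluded when it is fully blank or contains any maximal
#' blank run strictly longer than `blank_s` seconds (0.5 s, i.e. 125 samples
#' at 250 Hz; a run of exactly 125 samples is kept). "Blank" means an
#' exactly-zero or missing (NaN/NA) sample, the two forms in which
#' patient-monitor transmission gaps arrive.
#'
#' @param seg An [ecg_segment()].
#' @param blank_s Maximum tolerated blank-run duration in seconds.
#' @param duration_s Expected segment duration; a segment of any other length
#'   is rejected as malformed.
#' @return A list with `kept` (logical) and `reason` (`NA`, `"fully_blank"`
#'   or `"blank_run_gt_half_s"`).
#' @export
filter_segment <- function(seg, blank_s = 0.5, duration_s = 20) {
  stopifnot(inherits(seg, "ecg_segment"))
  n_expect <- as.integer(round(seg$fs_hz * duration_s))
  if (length(seg$values) != n_expect)
    stop(sprintf("malformed segment: expected %d samples, got %d",
                 n_expect, length(seg$values)), call. = FALSE)
  blank <- is.na(seg$values) | seg$values == 0
  if (all(blank))
    return(list(kept = FALSE, reason = "fully_blank"))
  runs <- rle(blank)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  if (max_run > blank_s * seg$fs_hz)
    return(list(kept = FALSE, reason = "blank_run_gt_half_s"))
  list(kept = TRUE, reason = NA_character_)
}

#' Zero out extreme amplitudes
#'
#' Samples whose magnitude exceeds `clip_mv` (±5 mV by default) are set to 0;
#' abruptly appearing extreme values beyond ±100 mV occur in raw
#' patient-monitor recordings and are removed this way rather than truncated.
#'
#' @param seg An [ecg_segment()].
#' @param clip_mv Cutoff magnitude in mV.
#' @return A list with `segment` (the cleaned [ecg_segment()]) and
#'   `n_clipped` (number of samples replaced).
#' @export
clip_extremes <- function(seg, clip_mv = 5) {
  stopifnot(inherits(seg, "ecg_segment"))
  v <- seg$values
  idx <- !is.na(v) & abs(v) > clip_mv
  v[idx] <- 0
  seg$values <- v
  list(segment = seg, n_clipped = sum(idx))
}

#' Interpolate isolated zero samples
#'
#' Every zero sample whose two immediate neighbours are both nonzero is
#' replaced by the linear midpoint of those neighbours. Runs of two or more
#' zeros and zeros at the segment boundary (which lack two neighbours) are
#' left untouched; long gaps are handled by [filter_segment()] instead.
#' Neighbour status is assessed on the input signal, so the operation is a
#' single simultaneous pass.
#'
#' @param seg An [ecg_segment()].
#' @return A list with `segment` and `n_interpolated`.
#' @export
interpolate_single_zeros <- function(seg) {
  stopifnot(inherits(seg, "ecg_segment"))
  v <- seg$values
  n <- length(v)
  if (n >= 3) {
    i <- 2:(n - 1)
    isolated <- v[i] == 0 & v[i - 1] != 0 & v[i + 1] != 0
    isolated[is.na(isolated)] <- FALSE
    pos <- i[isolated]
    v[pos] <- (v[pos - 1] + v[pos + 1]) / 2
  } else {
    pos <- integer(0)
  }
  seg$values <- v
  list(segment = seg, n_interpolated = length(pos))
}

#' Clean a batch of segments
#'
#' Applies the fixed cleaning chain per segment: blank-run exclusion, then
#' ±`clip_mv` extreme-value zeroing, then isolated-zero interpolation.
#' Missing samples inside kept segments are treated as zeros before clipping.
#' Kept segments keep their length and, after the chain, contain no sample
#' with magnitude above `clip_mv`.
#'
#' @param segments List of [ecg_segment()]s (optionally named).
#' @param blank_s,clip_mv,duration_s Cleaning thresholds, see
#'   [filter_segment()] and [clip_extremes()].
#' @return A list with `kept` (named list of cleaned segments) and `report`
#'   (`data.frame` with segment_id, kept, reason, n_clipped, n_interpolated),
#'   plus `n_excluded` and `fraction_excluded`.
#' @export
preprocess_batch <- function(segments, blank_s = 0.5, clip_mv = 5,
                             duration_s = 20) {
  ids <- names(segments)
  if (is.null(ids)) ids <- sprintf("seg_%05d", seq_along(segments))
  kept <- list()
  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    f <- filter_segment(seg, blank_s = blank_s, duration_s = duration_s)
    if (!f$kept) {
      rows[[i]] <- data.frame(segment_id = ids[i], kept = FALSE,
                              reason = f$reason, n_clipped = NA_integer_,
                              n_interpolated = NA_integer_)
      next
    }
    seg$values[is.na(seg$values)] <- 0
    cl <- clip_extremes(seg, clip_mv = clip_mv)
    ip <- interpolate_single_zeros(cl$segment)
    kept[[ids[i]]] <- ip$segment
    rows[[i]] <- data.frame(segment_id = ids[i], kept = TRUE,
                            reason = NA_character_, n_clipped = cl$n_clipped,
                            n_interpolated = ip$n_interpolated)
  }
  report <- do.call(rbind, rows)
  if (is.null(report))
    report <- data.frame(segment_id = character(0), kept = logical(0),
                         reason = character(0), n_clipped = integer(0),
                         n_interpolated = integer(0))
  n_excluded <- sum(!report$kept)
  list(kept = kept, report = report, n_excluded = n_excluded,
       fraction_excluded = if (nrow(report) > 0) n_excluded / nrow(report) else 0)
}
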