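# 2D input representations for the convolutional classifiers. All three
# transforms are deterministic and produce an 80 x 100 matrix.

INPUT_ROWS <- 80L
INPUT_COLS <- 100L

input_matrix <- function(values, kind) {
  stopifnot(is.matrix(values), nrow(values) == INPUT_ROWS,
            ncol(values) == INPUT_COLS, all(is.finite(values)))
  structure(values, kind = kind)
}

check_standard_length <- function(seg) {
  stopifnot(inherits(seg, "ecg_segment"))
  if (length(seg$values) != 5000L)
    stop("transform requires a 5000-sample segment", call. = FALSE)
}

# Linear resampling of a matrix to a fixed grid along both axes.
resample_matrix <- function(m, rows, cols) {
  r1 <- apply(m, 2, function(col) {
    if (length(col) == rows) col else
      stats::approx(seq_along(col), col, n = rows)$y
  })
  r1 <- matrix(r1, nrow = rows)
  out <- t(apply(r1, 1, function(row) {
    if (length(row) == cols) row else
      stats::approx(seq_along(row), row, n = cols)$y
  }))
  matrix(out, nrow = rows, ncol = cols)
}

#' Sliding-window matrix representation
#'
#' The 5000-sample segment is cut into windows of length 10 with a step of 5
#' samples (999 windows), the windows are concatenated in order (9990
#' values), uniformly decimated to 8000 values, and reshaped row-major into
#' an 80 x 100 matrix. The decimation-and-reshape step is isolated here so
#' the mapping can be swapped if a different convention is preferred.
#'
#' @param seg A 5000-sample [ecg_segment()].
#' @return An 80 x 100 matrix with `kind` attribute `"raw_window"`.
#' @export
sliding_window_matrix <- function(seg) {
  check_standard_length(seg)
  x <- seg$values
  starts <- seq(1L, 5000L - 10L + 1L, by = 5L)        # 999 windows
  idx <- rep(starts, each = 10L) + rep(0:9, times = length(starts))
  vals <- x[idx]                                      # 9990 values
  pick <- round(seq(1, length(vals), length.out = INPUT_ROWS * INPUT_COLS))
  input_matrix(matrix(vals[pick], nrow = INPUT_ROWS, ncol = INPUT_COLS,
                      byrow = TRUE), kind = "raw_window")
}

time_frequency_image <- function(seg, kind_label, window_kind) {
  check_standard_length(seg)
  st <- stft_mag(seg$values, seg$fs_hz, window = 100, overlap = 50,
                 kind = window_kind)
  m <- resample_matrix(st$mag, INPUT_ROWS, INPUT_COLS)
  input_matrix(m, kind = kind_label)
}

#' STFT magnitude image
#'
#' Magnitude of the short-time Fourier transform (periodic Hann window of
#' 100 samples, 50% overlap) mapped to the fixed 80 x 100 grid by linear
#' resampling: rows are the one-sided frequency axis (0 to fs/2), columns
#' the time frames. Input representation of the one-step 3-class CNN.
#'
#' @param seg A 5000-sample [ecg_segment()].
#' @return An 80 x 100 matrix with `kind` attribute `"stft"`.
#' @export
stft_image <- function(seg) time_frequency_image(seg, "stft", "hann")

#' Windowed-FFT magnitude image
#'
#' Same time-frequency mapping as [stft_image()] but with an untapered
#' (rectangular) 100-sample window, i.e. plain FFTs of successive windows.
#' Input representation of the binary CNNs in the two-step approach.
#'
#' @param seg A 5000-sample [ecg_segment()].
#' @return An 80 x 100 matrix with `kind` attribute `"fft"`.
#' @export
fft_image <- function(seg) time_frequency_image(seg, "fft", "rect")

#' Frequency axis of the time-frequency images
#'
#' @return Numeric vector of length 80: the frequency (Hz) represented by
#'   each image row, for a 250 Hz segment.
#' @export
image_freq_axis <- function() seq(0, 125, length.out = INPUT_ROWS)

#' Apply a transform to a batch of segments
#'
#' @param segments List of [ecg_segment()]s.
#' @param mode One of `"window"`, `"stft"`, `"fft"`.
#' @return A 3-d array (80, 100, n) of stacked input matrices.
#' @export
transform_batch <- function(segments, mode = c("stft", "fft", "window")) {
  mode <- match.arg(mode)
  f <- switch(mode, stft = stft_image, fft = fft_image,
              window = sliding_window_matrix)
  arr <- vapply(segments, function(s) unclass(f(s)),
                matrix(0, INPUT_ROWS, INPUT_COLS))
  array(arr, dim = c(INPUT_ROWS, INPUT_COLS, length(segments)),
        dimnames = list(NULL, NULL, names(segments)))
}
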