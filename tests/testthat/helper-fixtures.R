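# Programmatic fixtures shared across tests.

clean_spec <- function(seed = 1, hr = 60, ...) {
  segment_spec(heart_rate_bpm = hr, seed = seed, ...)
}

# a short (fs = 50 Hz, 20 s = 1000 samples) segment for brute-force feature
# cross-checks, where quadratic-cost oracles stay cheap
short_noisy_segment <- function(seed = 42) {
  generate_segment(segment_spec(heart_rate_bpm = 72, fs_hz = 50L,
                                noise_sigma_mv = 0.1,
                                wander_amplitude_mv = 0.3,
                                seed = seed))
}

# segment with an exact blank run of `len` samples starting at `at`
segment_with_blank <- function(len, at = 1000, seed = 2) {
  seg <- generate_segment(clean_spec(seed = seed))
  if (len > 0) seg$values[at:(at + len - 1)] <- 0
  seg
}

# separable synthetic image set: two classes whose means differ by 5 sigma
# in a block of pixels
separable_images <- function(n_per_class, sigma = 0.1, seed = 11) {
  withr::with_seed(seed, {
    mu <- matrix(0, 80, 100)
    mu[20:40, 30:60] <- 5 * sigma
    X <- array(rnorm(80 * 100 * 2 * n_per_class, 0, sigma),
               c(80, 100, 2 * n_per_class))
    for (i in seq_len(n_per_class)) X[, , i] <- X[, , i] + mu
    list(images = X,
         labels = factor(rep(c("acceptable", "unacceptable"),
                             each = n_per_class)))
  })
}
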