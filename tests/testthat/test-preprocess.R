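make_seg <- function(values) ecg_segment(values, fs_hz = 250L)

flatline <- function(fill = 0.1, n = 5000) rep(fill, n)

test_that("blank-run exclusion follows the strict half-second rule", {
  expect_false(filter_segment(make_seg(rep(0, 5000)))$kept)
  expect_identical(filter_segment(make_seg(rep(0, 5000)))$reason,
                   "fully_blank")
  v <- flatline()
  v[100:225] <- 0  # 126 samples = 0.504 s > 0.5 s
  res <- filter_segment(make_seg(v))
  expect_false(res$kept)
  expect_identical(res$reason, "blank_run_gt_half_s")
  v <- flatline()
  v[100:224] <- 0  # 125 samples = exactly 0.5 s, kept
  expect_true(filter_segment(make_seg(v))$kept)
})

test_that("NaN samples count as blank", {
  v <- flatline()
  v[100:226] <- NaN
  expect_false(filter_segment(make_seg(v))$kept)
})

test_that("a malformed segment length is rejected", {
  expect_error(filter_segment(make_seg(rep(0.1, 4999))), "malformed")
})

test_that("extreme values are zeroed symmetrically at +-5 mV", {
  v <- flatline()
  v[10] <- 120; v[20] <- -6; v[30] <- 6; v[40] <- 5; v[50] <- -5
  res <- clip_extremes(make_seg(v))
  expect_identical(res$n_clipped, 3L)
  expect_identical(res$segment$values[c(10, 20, 30)], c(0, 0, 0))
  expect_identical(res$segment$values[c(40, 50)], c(5, -5))  # boundary kept
  # no-op case
  res2 <- clip_extremes(make_seg(flatline()))
  expect_identical(res2$n_clipped, 0L)
  expect_identical(res2$segment$values, flatline())
})

test_that("only isolated interior zeros are linearly interpolated", {
  v <- flatline(0.1)
  v[100] <- 0                      # isolated: neighbours 0.1, 0.1
  v[200] <- 0; v[201] <- 0         # pair: untouched
  v[1] <- 0                        # boundary: untouched
  v[300] <- 0; v[299] <- 0.2       # isolated with asymmetric neighbours
  res <- interpolate_single_zeros(make_seg(v))
  expect_identical(res$n_interpolated, 2L)
  expect_equal(res$segment$values[100], 0.1)
  expect_equal(res$segment$values[300], (0.2 + 0.1) / 2)
  expect_identical(res$segment$values[c(1, 200, 201)], c(0, 0, 0))
})

test_that("the tiny worked example interpolates to the midpoint", {
  r <- interpolate_single_zeros(ecg_segment(c(0.1, 0, 0.2), fs_hz = 1L))
  expect_equal(r$segment$values, c(0.1, 0.15, 0.2))
  r2 <- interpolate_single_zeros(ecg_segment(c(0.1, 0, 0, 0.2), fs_hz = 1L))
  expect_equal(r2$segment$values, c(0.1, 0, 0, 0.2))
  r3 <- interpolate_single_zeros(ecg_segment(c(0, 0.1, 0.2), fs_hz = 1L))
  expect_equal(r3$segment$values, c(0, 0.1, 0.2))
})

test_that("clipping and interpolation are idempotent", {
  set.seed(5)
  v <- rnorm(5000, 0, 3)
  s1 <- clip_extremes(make_seg(v))$segment
  s2 <- clip_extremes(s1)$segment
  expect_identical(s1$values, s2$values)
  i1 <- interpolate_single_zeros(s1)$segment
  i2 <- interpolate_single_zeros(i1)$segment
  expect_identical(i1$values, i2$values)
})

test_that("the full chain keeps length and bounds all magnitudes at 5 mV", {
  set.seed(8)
  segs <- replicate(10, make_seg(rnorm(5000, 0, 4)), simplify = FALSE)
  out <- preprocess_batch(segs)
  for (s in out$kept) {
    expect_length(s$values, 5000)
    expect_true(all(abs(s$values) <= 5))
  }
})

test_that("batch report counts exclusions exactly", {
  segs <- list(
    a = make_seg(flatline()),
    b = make_seg(rep(0, 5000)),                          # fully blank
    c = segment_with_blank(126),                         # long blank
    d = segment_with_blank(300),                         # long blank
    e = segment_with_blank(125),                         # exactly 0.5 s: kept
    f = generate_segment(clean_spec(seed = 3))
  )
  out <- preprocess_batch(segs)
  expect_identical(out$n_excluded, 3L)
  expect_equal(out$fraction_excluded, 0.5)
  expect_named(out$kept, c("a", "e", "f"))
  expect_identical(out$report$segment_id, names(segs))
  # empty batch
  empty <- preprocess_batch(list())
  expect_identical(empty$kept, list())
  expect_identical(nrow(empty$report), 0L)
  expect_identical(empty$fraction_excluded, 0)
})

test_that("NaNs inside kept segments become zeros before clipping", {
  v <- flatline()
  v[100] <- NaN
  out <- preprocess_batch(list(make_seg(v)))
  # the NaN became 0, then an isolated zero, then interpolated
  expect_identical(out$report$n_interpolated, 1L)
  expect_equal(out$kept[[1]]$values[100], 0.1)
})
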