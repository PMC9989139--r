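make_series <- function(data, fs = 250) {
  # data: trial x roi x sample
  structure(list(subject = "S01", condition = "CS+", data = data, fs = fs,
                 t0_index = 63L,
                 roi_names = sprintf("ROI%02d", seq_len(dim(data)[2]))),
            class = "epoched_series")
}

sinusoid_series <- function(freq, n = 1000, fs = 250) {
  t <- (seq_len(n) - 1) / fs
  arr <- array(0, dim = c(1, 1, n))
  arr[1, 1, ] <- sin(2 * pi * freq * t)
  make_series(arr, fs)
}

steady <- function(x) x[200:(length(x) - 200)]

test_that("band-pass filter preserves passband and rejects stopband", {
  s20 <- bandpass_filter(sinusoid_series(20))
  amp <- max(abs(steady(s20$data[1, 1, ])))
  expect_gt(amp, 0.95)   # < 5% attenuation at 20 Hz in 3-45 Hz band
  s1 <- bandpass_filter(sinusoid_series(1))
  expect_lt(max(abs(steady(s1$data[1, 1, ]))), 0.1)  # > 90% attenuation at 1 Hz
  # idempotence in the passband
  s20b <- bandpass_filter(s20)
  d <- steady(s20$data[1, 1, ]) - steady(s20b$data[1, 1, ])
  expect_lt(sqrt(mean(d^2)) / sqrt(mean(steady(s20$data[1, 1, ])^2)), 0.01)
})

test_that("filtering is linear and validates its band edges", {
  set.seed(4)
  x <- rnorm(500); y <- rnorm(500)
  fx <- bandpass_filter(x, 3, 45, fs = 250)
  fy <- bandpass_filter(y, 3, 45, fs = 250)
  fxy <- bandpass_filter(2 * x + 3 * y, 3, 45, fs = 250)
  expect_equal(fxy, 2 * fx + 3 * fy, tolerance = 1e-10)
  expect_error(bandpass_filter(x, 3, 130, fs = 250), "Nyquist")
  expect_error(bandpass_filter(x, 0, 45, fs = 250), "low_hz")
  expect_warning(out <- bandpass_filter(x, 3, 125, fs = 250), "vacuous")
  expect_identical(out, x)
})

abind_3 <- function(...) {
  blocks <- list(...)
  arr <- array(0, dim = c(dim(blocks[[1]])[1], dim(blocks[[1]])[2],
                          sum(vapply(blocks, function(b) dim(b)[3], numeric(1)))))
  at <- 0
  for (b in blocks) {
    arr[, , at + seq_len(dim(b)[3])] <- b
    at <- at + dim(b)[3]
  }
  arr
}

test_that("window slicing follows the rounding convention and conserves samples", {
  arr <- array(seq_len(2 * 3 * 438), dim = c(2, 3, 438))
  ser <- make_series(arr)
  blocks <- slice_windows(ser)
  expect_equal(dim(blocks$baseline)[3], 62)
  post <- blocks[paste0("T", 1:6)]
  expect_equal(sum(vapply(post, function(b) dim(b)[3], numeric(1))), 375)
  # disjoint and contiguous: concatenation reproduces the raw 0-1500 ms span
  cat_post <- do.call(abind_3, post)
  expect_equal(cat_post, arr[, , 63:437, drop = FALSE], ignore_attr = TRUE)
  # empty scheme, out-of-epoch window
  expect_length(slice_windows(ser, window_scheme()[0, ]), 0)
  bad <- data.frame(name = "late", start_ms = 1400, end_ms = 1800)
  expect_error(slice_windows(ser, bad), "late")
})

test_that("each 250-ms window partitions exactly into five 50-ms subwindows", {
  sc <- window_scheme()
  for (k in seq_len(nrow(sc))) {
    off <- subwindow_offsets(sc$start_ms[k], sc$end_ms[k], fs = 250)
    expect_equal(nrow(off), 5)
    # contiguous
    expect_equal(off$start_offset[-1], off$end_offset[-5])
    # covers the parent window exactly
    expect_equal(off$start_offset[1], threatnets:::ms_to_offset(sc$start_ms[k], 250))
    expect_equal(off$end_offset[5], threatnets:::ms_to_offset(sc$end_ms[k], 250))
  }
})

test_that("condition contrast equals elementwise subtraction", {
  keys <- expand.grid(subject = c("a", "b"), window = c("T1", "T2"),
                      stringsAsFactors = FALSE)
  tp <- cbind(keys, value = c(1, 2, 3, 4))
  tm <- cbind(keys, value = c(1, 2, 3, 4))
  expect_equal(condition_contrast(tp, tm)$value, rep(0, 4))
  tp2 <- tp; tp2$value <- tm$value + 1
  expect_equal(condition_contrast(tp2, tm)$value, rep(1, 4))
  set.seed(5)
  tp3 <- tp; tp3$value <- rnorm(4)
  tm3 <- tm; tm3$value <- rnorm(4)
  # shuffled row order must not matter
  tm3s <- tm3[c(3, 1, 4, 2), ]
  got <- condition_contrast(tp3, tm3s)
  expect_equal(got$value, tp3$value - tm3$value)
  tm4 <- tm3[-2, ]
  expect_error(condition_contrast(tp3, tm4), "key mismatch")
})

test_that("ITPC is 1 for identical trials, near chance for random phases, bounded", {
  fs <- 250; n <- 500
  t <- (seq_len(n) - 1) / fs
  one <- sin(2 * pi * 6 * t)
  arr <- array(0, dim = c(10, 1, n))
  for (tr in 1:10) arr[tr, 1, ] <- one
  v <- itpc(make_series(arr), roi = 1, band = c(4, 8))
  expect_equal(v, rep(1, n), tolerance = 1e-6)
  # independent trials (noise-driven phases), n = 100: chance level of the
  # resultant length is 0.886 / sqrt(100); phase decorrelation over time
  # averages the per-sample draws toward it
  set.seed(8)
  arr2 <- array(rnorm(100 * n), dim = c(100, 1, n))
  v2 <- itpc(make_series(arr2), roi = 1, band = c(4, 8))
  expect_true(all(v2 >= 0 & v2 <= 1))
  expect_lt(abs(mean(steady(v2)) - 0.0886) / 0.0886, 0.2)
  expect_error(itpc(make_series(arr2[1, , , drop = FALSE]), 1, c(4, 8)),
               "2 trials")
})
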