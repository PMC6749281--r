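test_that("extract_epochs cuts half-open windows of the expected length", {
  # ramp recording: sample value equals its 0-based index
  rec <- matrix(rep(0:999, each = 2), 2, 1000, byrow = FALSE)
  rec <- rbind(0:999, 0:999 + 0.5)

  es <- extract_epochs(rec, cue_times = c(1, 4, 6.5), window = c(0.5, 2.5),
                       fs = 100)
  expect_equal(dim(es), c(3L, 2L, 200L))

  # cue 0, window [0,1): exactly samples 0..99
  es2 <- extract_epochs(rec, cue_times = 0, window = c(0, 1), fs = 100)
  expect_equal(as.numeric(es2$data[1, 1, ]), as.numeric(0:99))

  # window start honours the 0-based convention: cue 1 s + t0 0.5 s -> 150
  es3 <- extract_epochs(rec, cue_times = 1, window = c(0.5, 2.5), fs = 100)
  expect_equal(es3$data[1, 1, 1], 150)

  # constant recording passes through untouched
  expect_true(all(extract_epochs(matrix(7, 1, 300), 0.5, c(0, 1),
                                 fs = 100)$data == 7))
})

test_that("extract_epochs rejects bad windows with informative errors", {
  rec <- matrix(rnorm(2 * 400), 2)
  expect_error(extract_epochs(rec, cue_times = c(0.5, 3), window = c(0.5, 2.5),
                              fs = 100), "t = 3")
  expect_error(extract_epochs(rec, cue_times = 0.5, window = c(2.5, 0.5),
                              fs = 100), "t0 < t1")
})

test_that("bandpass matches the designed filter's amplitude response", {
  fs <- 100
  band <- band_spec(8, 12)
  inband <- sinusoid_epochs(10, fs = fs)
  out <- bandpass(inband, band)
  gain <- filtfilt_gain(band, fs, 10)
  # discard edges: zero-phase filtering still rings near the ends
  mid <- 101:400
  r_in <- rms(inband$data[1, 1, mid])
  r_out <- rms(out$data[1, 1, mid])
  expect_lt(abs(r_out / r_in - gain), 0.05)
  expect_lt(abs(r_out / r_in - 1), 0.05)     # 10 Hz sits in the passband

  stopb <- bandpass(sinusoid_epochs(30, fs = fs), band)
  expect_lt(rms(stopb$data[1, 1, mid]) / r_in, 0.05)
})

test_that("bandpass maps zero to zero and is idempotent in the passband", {
  z <- epoch_set(array(0, c(2, 2, 300)), labels = 1:2, fs = 100)
  expect_equal(max(abs(bandpass(z, band_spec(8, 12))$data)), 0)

  once <- bandpass(sinusoid_epochs(10), band_spec(8, 12))
  twice <- bandpass(once, band_spec(8, 12))
  mid <- 101:400
  rel <- rms(twice$data[1, 1, mid] - once$data[1, 1, mid]) /
    rms(once$data[1, 1, mid])
  expect_lt(rel, 0.01)
})

test_that("bandpass rejects invalid bands and too-short epochs", {
  es <- sinusoid_epochs(10, fs = 100, N = 300)
  expect_error(bandpass(es, band_spec(8, 60)), "Nyquist")
  short <- epoch_set(array(rnorm(2 * 2 * 10), c(2, 2, 10)), labels = 1:2,
                     fs = 100)
  expect_error(bandpass(short, band_spec(8, 12)), "too short")
})

test_that("matrix filtering agrees with the reference vector implementation", {
  set.seed(11)
  x <- rnorm(400)
  co <- fbcsp:::butter_coefs(band_spec(8, 12), 100)
  mine <- fbcsp:::filtfilt_mat(co$b, co$a, matrix(x, ncol = 1))[, 1]
  ref <- signal::filtfilt(signal::butter(2, c(8, 12) / 50, type = "pass"), x)
  # implementations differ in edge handling; compare away from the edges
  mid <- 101:300
  expect_lt(max(abs(mine[mid] - ref[mid])) / rms(x), 0.02)
})

test_that("default filter bank is the eight contiguous 4-Hz bands", {
  fb <- default_filterbank()
  expect_s3_class(fb, "filter_bank")
  expect_length(fb, 8L)
  lows <- vapply(fb, `[[`, numeric(1), "low_hz")
  highs <- vapply(fb, `[[`, numeric(1), "high_hz")
  expect_identical(lows, seq(4, 32, by = 4))
  expect_identical(highs, seq(8, 36, by = 4))
  expect_true(all(highs - lows == 4))
  expect_identical(fb, default_filterbank())   # bit-identical across calls
})

test_that("epoch_set enforces its invariants", {
  x <- array(rnorm(4 * 2 * 30), c(4, 2, 30))
  expect_error(epoch_set(x, labels = rep(1, 4), fs = 100), "both classes")
  expect_error(epoch_set(x, labels = c(1, 2, 3, 1), fs = 100), "values in")
  x[1, 1, 1] <- NA
  expect_error(epoch_set(x, labels = rep(1:2, 2), fs = 100), "non-finite")
})
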