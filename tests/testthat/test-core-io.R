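test_that("delimited bundle round-trip preserves data and metadata", {
  set.seed(1)
  rec <- recording(matrix(rnorm(4 * 1000, 0, 40), 4), 500,
                   channels = c("Cz", "C4", "ECG", "EMG"))
  path <- file.path(tempdir(), "bundle_rt")
  write_recording(rec, path)
  r2 <- read_recording(path, "bundle")
  expect_equal(r2$data, rec$data, tolerance = 1e-6)
  expect_identical(r2$channels, rec$channels)
  expect_identical(unname(r2$roles), unname(rec$roles))
  expect_equal(r2$rate, rec$rate)
  expect_identical(r2$units, rec$units)
})

test_that("EDF round-trip recovers channels, rate and data to quantisation", {
  set.seed(2)
  rec <- recording(matrix(rnorm(3 * 2500, 0, 50), 3), 500,
                   channels = c("Cz", "ECG", "EMG"))
  f <- file.path(tempdir(), "rt.edf")
  write_edf(rec, f)
  r2 <- read_recording(f, "edf")
  expect_equal(nrow(r2$data), 3)
  expect_equal(r2$rate, 500)
  expect_identical(r2$channels, rec$channels)
  # 16-bit quantisation of the per-channel range
  qstep <- (apply(rec$data, 1, max) - apply(rec$data, 1, min)) / 65535
  expect_true(all(abs(r2$data - rec$data) <= qstep + 1e-12))
})

test_that("unreadable and truncated files raise I/O errors naming the path", {
  expect_error(read_recording("/nonexistent/dir", "bundle"), "nonexistent")
  expect_error(read_edf("/nonexistent/file.edf"), "nonexistent")
  f <- file.path(tempdir(), "trunc.edf")
  rec <- recording(matrix(rnorm(2 * 1000), 2), 250, channels = c("Cz", "C3"))
  write_edf(rec, f)
  full <- readBin(f, raw(), file.info(f)$size)
  writeBin(full[1:(length(full) - 500)], f)
  expect_error(read_edf(f), "truncated")
})

test_that("events round-trip through TSV with metadata", {
  ev <- event_list(onset_s = c(2.5, 1.0, 3.2), label = c("tms", "tms", "sham"),
                   distance_ms = c(120, 300, NA), phase = c("systole", "diastole", NA))
  expect_equal(ev$onset_s, c(1.0, 2.5, 3.2))  # sorted
  f <- file.path(tempdir(), "ev.tsv")
  write_events(ev, f)
  ev2 <- read_events(f)
  expect_equal(ev2$onset_s, ev$onset_s)
  expect_equal(ev2$label, ev$label)
  expect_equal(ev2$distance_ms, ev$distance_ms)
  expect_equal(ev2$phase, ev$phase)
})

test_that("epoching: counts, drops and baseline correction", {
  rate <- 250
  rec <- one_ch_rec(rep(7, 20 * rate), rate)
  ev <- event_list(onset_s = c(0.1, seq(3, 12, by = 1)), label = "tms")
  ep <- epoch(rec, ev, "tms", -1.4, 1.0)
  expect_equal(dim(ep$data)[1], 10)            # event at 0.1 s dropped
  expect_equal(ep$n_dropped, 1)
  expect_equal(dim(ep$data)[1] + ep$n_dropped, nrow(ev))
  # constant signal, baseline given -> all zero
  epb <- epoch(rec, ev, "tms", -1.4, 1.0, baseline_window = c(-0.11, -0.01))
  expect_true(all(abs(epb$data) < 1e-12))
  expect_error(epoch(rec, ev, "sham", -1, 1), "no events")
  ev2 <- event_list(onset_s = 0.1, label = "tms")
  expect_error(epoch(rec, ev2, "tms", -1.4, 1.0), "zero usable")
})

test_that("band-pass removes DC, notch attenuates 50 Hz >= 40 dB, passband flat", {
  rate <- 1000
  t <- seq(0, 6, by = 1 / rate)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  dc <- bandpass_notch(one_ch_rec(rep(10, length(t)), rate))$data[1, ]
  expect_lt(abs(mean(dc[mid])), 0.1)
  y50 <- bandpass_notch(one_ch_rec(sin(2 * pi * 50 * t), rate))$data[1, ]
  expect_lt(sqrt(mean(y50[mid]^2)), 10^(-40 / 20))
  y10 <- bandpass_notch(one_ch_rec(sin(2 * pi * 10 * t), rate))$data[1, ]
  expect_lt(abs(max(abs(y10[mid])) - 1), 0.05)
  expect_error(bandpass_notch(one_ch_rec(rnorm(5000), rate), band = c(0.5, 600)),
               "Nyquist")
})

test_that("filtering is stable at the 5 kHz acquisition rate", {
  # a 20 s trace leaves the 0.5 Hz high-pass transient outside the middle
  rate <- 5000
  t <- seq(0, 20, by = 1 / rate)
  y <- bandpass_notch(one_ch_rec(10 + sin(2 * pi * 10 * t), rate))$data[1, ]
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  expect_lt(max(abs(y[mid])), 1.1)
  expect_lt(abs(mean(y[mid])), 0.1)
})

test_that("filtering and re-referencing are linear operators", {
  rate <- 500
  set.seed(3)
  x <- rnorm(3000); y <- rnorm(3000)
  f <- function(v) bandpass_notch(one_ch_rec(v, rate))$data[1, ]
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-6)
})

test_that("mastoid re-referencing subtracts (a+b)/2 from EEG only", {
  set.seed(4)
  d <- matrix(rnorm(5 * 100), 5)
  chs <- c("Cz", "C4", "M1", "M2", "ECG")
  rec <- recording(d, 100, channels = chs)
  rr <- rereference_mastoids(rec, "M1", "M2")
  ref <- (d[3, ] + d[4, ]) / 2
  expect_equal(rr$data[1, ], d[1, ] - ref)
  expect_equal(rr$data[2, ], d[2, ] - ref)
  expect_equal(rr$data[5, ], d[5, ])           # ECG untouched
  # zero mastoids: identity
  d0 <- d; d0[3:4, ] <- 0
  rr0 <- rereference_mastoids(recording(d0, 100, channels = chs), "M1", "M2")
  expect_equal(unname(rr0$data), unname(d0))
  # mastoids identical to channel -> that channel zero
  d1 <- d; d1[3, ] <- d1[1, ]; d1[4, ] <- d1[1, ]
  rr1 <- rereference_mastoids(recording(d1, 100, channels = chs), "M1", "M2")
  expect_equal(rr1$data[1, ], rep(0, 100))
  expect_error(rereference_mastoids(rec, "M1", "M9"), "mastoid")
})

test_that("downsampling preserves in-band tones and rejects out-of-band ones", {
  rate <- 5000
  t <- seq(0, 4, by = 1 / rate)
  r5 <- downsample(one_ch_rec(sin(2 * pi * 5 * t), rate), 500)
  expect_equal(r5$rate, 500)
  mid <- seq(round(ncol(r5$data) * 0.25), round(ncol(r5$data) * 0.75))
  expect_lt(abs(max(abs(r5$data[1, mid])) - 1), 0.02)
  # spectral peak at 5 Hz
  sp <- stats::spec.pgram(r5$data[1, ], plot = FALSE, taper = 0)
  expect_lt(abs(sp$freq[which.max(sp$spec)] * 500 - 5), 0.3)
  # constant stays constant
  rc <- downsample(one_ch_rec(rep(3, length(t)), rate), 500)
  expect_equal(rc$data[1, mid], rep(3, length(mid)), tolerance = 1e-6)
  # 400 Hz above the new Nyquist: residual < 1 %
  r400 <- downsample(one_ch_rec(sin(2 * pi * 400 * t), rate), 500)
  expect_lt(max(abs(r400$data[1, mid])), 0.01)
  expect_error(downsample(one_ch_rec(rnorm(100), 100), 200), "target_rate")
})

test_that("non-integer downsampling preserves tone frequency within 0.1 Hz", {
  rate <- 750
  t <- seq(0, 8, by = 1 / rate)
  r <- downsample(one_ch_rec(sin(2 * pi * 11 * t), rate), 500)
  expect_equal(r$rate, 500)
  sp <- stats::spec.pgram(r$data[1, ], plot = FALSE, taper = 0, pad = 3)
  expect_lt(abs(sp$freq[which.max(sp$spec)] * 500 - 11), 0.1)
})
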