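test_that("stimulus-artifact interpolation: identity, ramp, spike removal", {
  rate <- 1000
  x <- seq(0, 10, length.out = 5000)          # linear ramp
  # no events -> identity
  expect_identical(interpolate_stim_artifact_ecg(x, numeric(0), rate), x)
  y <- interpolate_stim_artifact_ecg(x, c(1, 2.5), rate)
  expect_equal(y, x, tolerance = 1e-9)        # cubic reproduces linear
  # samples outside windows are bit-identical
  z <- x; z[2000:2005] <- 100                 # 5 ms spike at 2 s
  yz <- interpolate_stim_artifact_ecg(z, 2.0, rate)
  win <- 1996:2012
  expect_identical(yz[-win], z[-win])
  rms_before <- sqrt(mean((z[win] - x[win])^2))
  rms_after <- sqrt(mean((yz[win] - x[win])^2))
  expect_lt(rms_after, 0.1 * rms_before)
})

test_that("R-peak detection matches generator truth and is sign-invariant", {
  cfg <- small_cfg(seed = 13, rr_sd_ms = 0, systole_jitter_ms = 0)
  g <- gen_ecg(cfg, 60)
  rp <- detect_r_peaks(g$ecg, cfg$rate)
  truth <- g$r_peaks[g$r_peaks > min(rp) - 0.3 & g$r_peaks < max(rp) + 0.3]
  expect_equal(length(rp), length(truth))
  expect_lt(max(abs(rp - truth)) * 1000, 5)
  rp_inv <- detect_r_peaks(-g$ecg, cfg$rate)
  expect_equal(rp_inv, rp, tolerance = 2 / cfg$rate)
  set.seed(1)
  expect_error(detect_r_peaks(rnorm(10 * cfg$rate), cfg$rate), "quality|no R-peaks")
})

test_that("trapezoid T-end matches a dense exhaustive-argmax oracle", {
  rate <- 1000
  t <- seq(0, 1.2, by = 1 / rate)
  # one beat: R at 0.1 (tall spike), Gaussian T centred 0.35, sd 0.05
  x <- 1000 * exp(-((t - 0.1)^2) / (2 * 0.005^2)) +
    300 * exp(-((t - 0.35)^2) / (2 * 0.05^2))
  r_peaks <- 0.1
  te <- detect_t_end(x, r_peaks, rate)
  expect_false(is.na(te))
  # within [centre + 1.5 sd, centre + 3 sd]
  expect_gte(te, 0.35 + 1.5 * 0.05)
  expect_lte(te, 0.35 + 3 * 0.05)
  # independent brute-force trapezoid maximisation on the full grid
  search <- c(0.08, 0.45); ref_off <- 0.120
  lo <- round((0.1 + search[1]) * rate) + 1
  hi <- round((0.1 + search[2]) * rate) + 1
  x_m <- lo - 1 + which.max(x[lo:hi]); y_m <- x[x_m]
  x_r <- hi + round(ref_off * rate)
  cand <- (x_m + 1):(x_r - 1)
  areas <- 0.5 * (y_m - x[cand]) * (2 * x_r - cand - x_m)
  oracle <- (cand[which.max(areas)] - 1) / rate
  expect_lt(abs(te - oracle) * 1000, 15)
})

test_that("monotone-descending T tail: detector equals the oracle exactly", {
  rate <- 500
  t <- seq(0, 1.2, by = 1 / rate)
  x <- 1000 * exp(-((t - 0.1)^2) / (2 * 0.005^2)) +
    300 * pmax(0, pmin(1, (0.45 - t) / 0.2)) * (t > 0.15)
  te <- detect_t_end(x, 0.1, rate)
  lo <- round((0.1 + 0.08) * rate) + 1
  hi <- round((0.1 + 0.45) * rate) + 1
  x_m <- lo - 1 + which.max(x[lo:hi]); y_m <- x[x_m]
  x_r <- hi + round(0.120 * rate)
  cand <- (x_m + 1):(x_r - 1)
  areas <- 0.5 * (y_m - x[cand]) * (2 * x_r - cand - x_m)
  expect_equal(te, (cand[which.max(areas)] - 1) / rate)
})

test_that("flat ECG after the QRS flags the beat unusable", {
  rate <- 500
  t <- seq(0, 1.2, by = 1 / rate)
  x <- 1000 * exp(-((t - 0.1)^2) / (2 * 0.005^2))
  expect_true(is.na(detect_t_end(x, 0.1, rate)))
})

test_that("cardiac map: forced window arithmetic and overlap invariants", {
  m <- build_cardiac_map(c(0, 0.9), c(0.351, NA))
  expect_equal(m$sys_len[1], 0.351)
  expect_equal(m$dia_start[1], 0.9 - 0.351)
  expect_true(m$usable[1])
  expect_false(m$usable[2])                   # last beat: no next R
  # rr 0.6 with L 0.351 -> 2L > rr -> unusable
  m2 <- build_cardiac_map(c(0, 0.6), c(0.351, NA))
  expect_false(m2$usable[1])
  # equal-length, disjoint windows for usable beats
  cfg <- small_cfg(seed = 14)
  g <- gen_ecg(cfg, 40)
  map <- build_cardiac_map(g$r_peaks, g$t_ends)
  u <- map[map$usable, ]
  expect_true(all(abs((u$t_end - u$r_time) -
                        (u$r_time + u$rr - u$dia_start)) < 1e-12))
  expect_true(all(u$dia_start > u$t_end))
})

test_that("mean detected systole length tracks the generator's truth", {
  cfg <- small_cfg(seed = 15)
  g <- gen_ecg(cfg, 90)
  rp <- detect_r_peaks(g$ecg, cfg$rate)
  te <- detect_t_end(g$ecg, rp, cfg$rate)
  map <- build_cardiac_map(rp, te)
  est <- mean(map$sys_len[map$usable], na.rm = TRUE) * 1000
  truth <- mean(g$beats$sys_len) * 1000
  expect_lt(abs(est - truth), 15)
})

test_that("event classification follows the window definitions", {
  map <- build_cardiac_map(c(0, 0.9, 1.8), c(0.351, 1.251, NA))
  cls <- classify_events(c(0.1, 0.4, 0.7, 2.5), map)
  expect_equal(cls$phase, c("systole", "neither", "diastole", "neither"))
  expect_equal(cls$distance_ms[1], 100)
  expect_true(cls$out_of_range[4])
  # adding events with other labels does not perturb classification
  cls2 <- classify_events(c(0.1, 0.2, 0.4, 0.55, 0.7, 2.5), map)
  expect_equal(cls2$phase[c(1, 3, 5, 6)], cls$phase)
})

test_that("uniform events are equally likely to land in systole and diastole", {
  cfg <- small_cfg(seed = 16)
  g <- gen_ecg(cfg, 120)
  map <- build_cardiac_map(g$r_peaks, g$t_ends)
  set.seed(17)
  ev <- runif(10000, 1, max(g$r_peaks) - 1)
  cls <- classify_events(ev, map)
  n_s <- sum(cls$phase == "systole"); n_d <- sum(cls$phase == "diastole")
  p <- stats::binom.test(n_s, n_s + n_d, 0.5)$p.value
  expect_gt(p, 0.01)
})

test_that("IBI triplets: constant RR, injected deceleration, sham self-subtraction", {
  r <- seq(0, 30, by = 0.9)
  tri <- ibi_triplets(c(5.0, 10.3, 20.7), r, rep("systole", 3))
  expect_true(all(abs(as.matrix(tri[, c("ibi_pre", "ibi_tms", "ibi_post")]) - 900)
                  < 1e-9))
  # injected deceleration recovered from generator truth
  cfg <- small_cfg(seed = 18, n_tms = 200, ibi_decel_ms = 40, ibi_accel_ms = 30)
  tr <- gen_trial_stats(cfg)
  sys <- tr[tr$phase == "systole" & !is.na(tr$ibi_pre), ]
  expect_lt(abs(mean(sys$ibi_tms - sys$ibi_pre) - 40), 15)
  # sham == real -> corrected cells centred on zero
  corr <- ibi_sham_correct(tri, tri)
  expect_true(all(abs(as.matrix(corr[, c("ibi_pre", "ibi_tms", "ibi_post")]))
                  < 1e-9))
  expect_error(ibi_sham_correct(tri, tri[tri$phase == "diastole", ]), "sham cell")
})
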