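test_that("late-trial selection keeps distances >= 400 ms", {
  cls <- data.frame(onset_s = 1:3, distance_ms = c(350, 420, 500))
  sel <- select_late_tms_trials(cls)
  expect_equal(sel$keep, c(2, 3))
  expect_equal(sel$distances_s, c(0.420, 0.500))
  cls2 <- data.frame(onset_s = 1:2, distance_ms = c(100, 399))
  expect_error(select_late_tms_trials(cls2), "400")
  # generator tail fraction
  cfg <- small_cfg(seed = 50, n_tms = 300)
  tr <- gen_trial_stats(cfg)
  frac_true <- mean(tr$distance_ms >= 400, na.rm = TRUE)
  sel3 <- select_late_tms_trials(data.frame(distance_ms = tr$distance_ms))
  expect_equal(length(sel3$keep) / sum(!is.na(tr$distance_ms)), frac_true,
               tolerance = 1e-9)
})

test_that("mock-event template: determinism and near-zero for unlocked EEG", {
  set.seed(51)
  rate <- 250
  rec <- recording(matrix(rnorm(2 * 100 * rate), 2), rate,
                   channels = c("Cz", "CP2"))
  tms <- seq(10, 90, by = 2.3)
  dists <- runif(length(tms), 0.4, 0.7)
  t1 <- estimate_mock_artifact(rec, tms, dists, seed = 3)
  t2 <- estimate_mock_artifact(rec, tms, dists, seed = 3)
  expect_identical(t1$template, t2$template)
  # no TMS-locked content: template RMS at the averaging noise floor
  n_avg <- length(tms) * 10
  expect_lt(sqrt(mean(t1$template^2)), 3 / sqrt(n_avg))
})

test_that("template subtraction removes TMS-locked energy in the HEP window", {
  set.seed(52)
  rate <- 250; dur <- 240
  tms <- seq(5, dur - 5, by = 2.0)
  dists <- runif(length(tms), 0.4, 0.7)     # > 200 ms spread
  art <- 40 * exp(-(0:(2 * rate)) / rate / 0.8)
  x <- rnorm(dur * rate, 0, 1)
  for (t0 in tms) {
    i <- round(t0 * rate) + 1
    idx <- i:min(i + length(art) - 1, length(x))
    x[idx] <- x[idx] + art[seq_along(idx)]
  }
  rec <- recording(matrix(x, 1), rate, channels = "Cz")
  tmpl <- estimate_mock_artifact(rec, tms, dists, seed = 1, channels = "Cz")
  r_times <- tms - dists
  ep0 <- extract_hep(rec, r_times, NULL)
  ep1 <- extract_hep(rec, r_times, tmpl)
  w <- ep0$times >= 0.296 & ep0$times <= 0.400
  e0 <- mean(colMeans(ep0$data[, 1, w])^2)
  e1 <- mean(colMeans(ep1$data[, 1, w])^2)
  expect_lt(e1, 0.3 * e0)
})

test_that("HEP extraction: baseline zeroed, amplitude tracks injection", {
  cfg <- small_cfg(seed = 53, n_tms = 80, hep_amp_uv = 4, hep_mep_coupling = 0,
                   noise_sd = list(eeg = 1, ecg = 10, emg = 5))
  ses <- gen_session(cfg)
  tr <- ses$truth$trials
  late <- tr[tr$condition == "tms" & !is.na(tr$distance_ms) &
               tr$distance_ms >= 400, ]
  r_times <- late$onset_s - late$distance_ms / 1000
  hc <- hep_config(electrodes = intersect(hep_config()$electrodes,
                                          ses$recording$channels))
  ep <- extract_hep(ses$recording, r_times, NULL, hc)
  bl <- ep$times >= -0.1 & ep$times <= 0
  expect_lt(max(abs(apply(ep$data[, , bl], c(1, 2), mean))), 1e-9)
  # injected deflection visible in the test window on HEP electrodes
  jj <- match(intersect(hc$electrodes, ep$channels), ep$channels)
  w <- ep$times >= 0.3 & ep$times <= 0.39
  expect_gt(mean(ep$data[, jj, w]), 0.5)
})

test_that("MEP binning: contiguity, remainder rule, tie stability", {
  expect_equal(bin_by_mep(1:9), rep(1:3, each = 3))
  b10 <- bin_by_mep(1:10)
  expect_equal(as.integer(table(b10)), c(4, 3, 3))
  # partition property: sizes sum to total, bins ordered by amplitude
  set.seed(54)
  a <- rnorm(47)
  b <- bin_by_mep(a, 3)
  expect_equal(length(b), 47)
  expect_true(max(a[b == 1]) <= min(a[b == 3]))
  # ties: stable by trial index
  expect_equal(bin_by_mep(rep(1, 6), 3), rep(1:3, each = 2))
  expect_error(bin_by_mep(1:2, 3), "fewer trials")
})

test_that("HEP-MEP coupling direction: strong bin exceeds weak bin", {
  cfg <- small_cfg(seed = 55, n_tms = 120, hep_mep_coupling = 1.5,
                   noise_sd = list(eeg = 2, ecg = 10, emg = 5))
  ses <- gen_session(cfg)
  card <- cardiomotor:::.session_cardiac(ses$recording, ses$events)
  cls <- card$classified
  sel <- select_late_tms_trials(cls)
  tms_t <- cls$onset_s[sel$keep]
  hc <- hep_config(electrodes = intersect(hep_config()$electrodes,
                                          ses$recording$channels))
  tmpl <- estimate_mock_artifact(ses$recording, tms_t, sel$distances_s, hc,
                                 seed = 1, channels = hc$electrodes)
  ep <- extract_hep(ses$recording, tms_t - sel$distances_s, tmpl, hc)
  amps <- mep_amplitudes(epoch(ses$recording,
                               event_list(onset_s = tms_t, label = "tms"),
                               "tms", -0.2, 0.1))
  res <- hep_bin_contrast(ep, amps, hc)
  expect_gt(mean(res$contrast), 0)
  expect_equal(sort(unique(res$bins)), 1:3)
})

test_that("adding an R-locked waveform shifts the HEP but not the template", {
  set.seed(56)
  rate <- 250; dur <- 120
  tms <- seq(5, dur - 5, by = 2.0)
  dists <- runif(length(tms), 0.4, 0.7)
  r_times <- tms - dists
  x <- rnorm(dur * rate, 0, 0.5)
  bump_t <- seq(0, 0.1, by = 1 / rate)
  bump <- 5 * sin(pi * bump_t / 0.1)^2
  y <- x
  for (r0 in r_times) {
    i <- round((r0 + 0.32) * rate) + 1
    idx <- i:(i + length(bump) - 1)
    y[idx] <- y[idx] + bump
  }
  rec_x <- recording(matrix(x, 1), rate, channels = "Cz")
  rec_y <- recording(matrix(y, 1), rate, channels = "Cz")
  t_x <- estimate_mock_artifact(rec_x, tms, dists, seed = 2, channels = "Cz")
  t_y <- estimate_mock_artifact(rec_y, tms, dists, seed = 2, channels = "Cz")
  # the R-locked bump is smeared across the template by the shuffle,
  # while the extracted HEP keeps it at full amplitude
  ep_y <- extract_hep(rec_y, r_times, t_y)
  w <- ep_y$times >= 0.33 & ep_y$times <= 0.40
  expect_gt(max(colMeans(ep_y$data[, 1, w])), 2.5)
  expect_lt(max(abs(t_y$template - t_x$template)), 2.5)
})
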