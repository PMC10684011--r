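#' Configuration for synthetic study sessions
#'
#' Defines the generative model for a complete synthetic session:
#' quasi-periodic ECG with R-peaks and T-waves, TMS/sham pulses at uniform
#' ISIs falling randomly over the cardiac cycle, MEPs whose log-amplitude
#' declines with time-from-R plus a multiplicative systolic boost, early
#' TEP deflections larger in systole, R-locked HEP deflections coupled to
#' the trial's MEP draw, TMS decay/pulse artifacts on all channels, and
#' phase-dependent interbeat-interval dynamics. Defaults mirror the study
#' conditions the package targets: 5 kHz sampling, 62-channel 10-10 EEG
#' plus mastoids, RR around 900 ms, systole around 350 ms, 416 real and
#' 416 sham pulses at 1.5-2.5 s ISIs.
#'
#' @param seed Integer; fully determines all generated output.
#' @param rate Sampling rate, Hz.
#' @param rr_mean_ms,rr_sd_ms Interbeat-interval mean and per-beat SD (ms).
#' @param systole_len_ms,systole_jitter_ms Mean and per-beat SD of the
#'   R-to-T-end interval (ms).
#' @param n_tms,n_sham Number of real and sham pulses.
#' @param isi_range_s Uniform inter-stimulus-interval range (s).
#' @param mep_base_uv Baseline MEP peak-to-peak amplitude (uV).
#' @param mep_systole_gain Multiplicative MEP gain for systolic pulses.
#' @param mep_distance_slope Log-amplitude decline per ms from the R-peak.
#' @param mep_log_noise_sd SD of the trial-level log-amplitude noise.
#' @param tep_amp_uv,tep_window_ms,tep_systole_gain Early TEP deflection
#'   amplitude, window (ms post-TMS) and systolic gain (hotspot channels).
#' @param hep_amp_uv,hep_window_ms,hep_mep_coupling HEP deflection
#'   amplitude, window (ms post-R) and coupling of the HEP amplitude to
#'   the trial's standardised MEP noise draw (uV per SD).
#' @param erd_depth Fractional 8-25 Hz power drop after pinch onset.
#' @param erd_systole_gain Multiplier on burst force and ERD depth for
#'   systolic pinch onsets.
#' @param ibi_decel_ms,ibi_accel_ms Lengthening of the cycle containing a
#'   systolic pulse and shortening of the next cycle (ms).
#' @param decay_amp_uv,decay_tau_ms,pulse_amp_uv,pulse_width_ms TMS
#'   artifact model (exponential decay and pulse spike), applied to real
#'   and sham alike.
#' @param noise_sd Named list of white-noise SDs per modality (uV).
#' @param eeg_channels EEG channel labels (mastoids appended if missing).
#' @param n_pinch Number of pinch trials for the motor task generator.
#' @param osc_amp_uv Amplitude of the ongoing sensorimotor oscillation.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(seed = 1L, rate = 5000,
                         rr_mean_ms = 900, rr_sd_ms = 50,
                         systole_len_ms = 350, systole_jitter_ms = 20,
                         n_tms = 416, n_sham = 416, isi_range_s = c(1.5, 2.5),
                         mep_base_uv = 500, mep_systole_gain = 1.3,
                         mep_distance_slope = 5e-4, mep_log_noise_sd = 0.4,
                         tep_amp_uv = 5, tep_window_ms = c(22, 60),
                         tep_systole_gain = 1.3,
                         hep_amp_uv = 2, hep_window_ms = c(296, 400),
                         hep_mep_coupling = 0.5,
                         erd_depth = 0.3, erd_systole_gain = 1.3,
                         ibi_decel_ms = 40, ibi_accel_ms = 30,
                         decay_amp_uv = 200, decay_tau_ms = 30,
                         pulse_amp_uv = 2000, pulse_width_ms = 2,
                         noise_sd = list(eeg = 5, ecg = 10, emg = 5),
                         eeg_channels = default_eeg_channels(),
                         n_pinch = 30, osc_amp_uv = 10) {
  cfg <- as.list(environment())
  stopifnot(cfg$rate > 0, cfg$rr_mean_ms > 2 * cfg$systole_len_ms,
            all(c(cfg$mep_systole_gain, cfg$tep_systole_gain,
                  cfg$erd_systole_gain) >= 0),
            cfg$erd_depth >= 0, cfg$erd_depth < 1)
  if (!all(c("M1", "M2") %in% cfg$eeg_channels))
    cfg$eeg_channels <- c(cfg$eeg_channels, setdiff(c("M1", "M2"), cfg$eeg_channels))
  cfg$seed <- as.integer(seed)
  class(cfg) <- "synth_config"
  cfg
}

# beat schedule: R times, per-beat systole lengths (R to T-end), RR.
# tms_sys: times of pulses whose beat-relative offset falls inside the true
# systole lengthen that beat's RR by ibi_decel and shorten the next by
# ibi_accel (phase-dependent cardiac response to stimulation).
.gen_beats <- function(cfg, duration_s, tms_times = numeric(0)) {
  if (duration_s * 1000 < 2 * cfg$rr_mean_ms)
    stop("duration too short for a single cardiac cycle")
  r <- 0.5
  beats_r <- c(); beats_l <- c(); beats_rr <- c()
  carry <- 0
  while (r < duration_s) {
    l <- stats::rnorm(1, cfg$systole_len_ms, cfg$systole_jitter_ms) / 1000
    l <- min(max(l, 0.2), 0.45)
    rr <- stats::rnorm(1, cfg$rr_mean_ms, cfg$rr_sd_ms) / 1000
    rr <- max(rr, 2 * l + 0.02)
    rr <- rr + carry
    carry <- 0
    hit <- any(tms_times >= r & tms_times <= r + l)
    if (hit) {
      rr <- rr + cfg$ibi_decel_ms / 1000
      carry <- -cfg$ibi_accel_ms / 1000
    }
    beats_r <- c(beats_r, r); beats_l <- c(beats_l, l); beats_rr <- c(beats_rr, rr)
    r <- r + rr
  }
  data.frame(r_time = beats_r, sys_len = beats_l, rr = beats_rr,
             t_end = beats_r + beats_l)
}

# ECG trace from a beat schedule: narrow biphasic QRS and a positive
# Gaussian T-wave whose analytic end (center + 2.5 sigma) equals the
# scheduled T-end.
.ecg_trace <- function(beats, rate, n_samp, noise_sd, t_sigma_s = 0.06) {
  tt <- (seq_len(n_samp) - 1) / rate
  ecg <- stats::rnorm(n_samp, 0, noise_sd)
  add_bump <- function(sig, center, sd, amp) {
    lo <- max(1, floor((center - 4 * sd) * rate) + 1)
    hi <- min(n_samp, ceiling((center + 4 * sd) * rate) + 1)
    if (lo > hi) return(sig)
    idx <- lo:hi
    sig[idx] <- sig[idx] + amp * exp(-((tt[idx] - center)^2) / (2 * sd^2))
    sig
  }
  for (k in seq_len(nrow(beats))) {
    r <- beats$r_time[k]
    ecg <- add_bump(ecg, r - 0.025, 0.006, -120)     # Q
    ecg <- add_bump(ecg, r, 0.007, 1000)             # R
    ecg <- add_bump(ecg, r + 0.030, 0.007, -200)     # S
    sigma <- min(t_sigma_s, beats$sys_len[k] / 3)
    center <- r + beats$sys_len[k] - 2.5 * sigma     # T: end at center+2.5*sigma
    ecg <- add_bump(ecg, center, sigma, 250)
  }
  ecg
}

#' Generate a synthetic ECG channel
#'
#' @param cfg A `synth_config`.
#' @param duration_s Trace duration, seconds.
#' @return List with `ecg` (numeric vector), `r_peaks`, `t_ends` (seconds)
#'   and the underlying `beats` schedule.
#' @export
gen_ecg <- function(cfg, duration_s = 60) {
  set.seed(cfg$seed)
  beats <- .gen_beats(cfg, duration_s)
  n_samp <- round(duration_s * cfg$rate)
  ecg <- .ecg_trace(beats, cfg$rate, n_samp, cfg$noise_sd$ecg)
  list(ecg = ecg, r_peaks = beats$r_time, t_ends = beats$t_end, beats = beats)
}

# windowed biphasic MEP template with unit peak-to-peak amplitude,
# spanning the 20-40 ms post-pulse window
.mep_shape <- function(rate) {
  n <- round(0.020 * rate)
  t <- seq(0, 1, length.out = n)
  w <- sin(2 * pi * t) * sin(pi * t)^2
  w / (max(w) - min(w))
}

.add_at <- function(sig, start_idx, shape) {
  n <- length(sig); m <- length(shape)
  lo <- max(1, start_idx); hi <- min(n, start_idx + m - 1)
  if (lo > hi) return(sig)
  sig[lo:hi] <- sig[lo:hi] + shape[(lo - start_idx + 1):(hi - start_idx + 1)]
  sig
}

# true phase under the equal-length window definition
.true_phase <- function(t, beats) {
  k <- findInterval(t, beats$r_time)
  if (k < 1 || k >= nrow(beats)) return(list(phase = "neither", distance_ms = NA, beat = k))
  off <- t - beats$r_time[k]
  l <- beats$sys_len[k]; rr <- beats$rr[k]
  phase <- if (off <= l) "systole"
           else if (off >= rr - l && off <= rr) "diastole"
           else "neither"
  list(phase = phase, distance_ms = off * 1000, beat = k)
}

#' Generate a full synthetic TMS session
#'
#' Emits a multichannel recording (EEG + ECG + EMG), the event stream and
#' the ground truth of every injected effect. Real pulses carry MEPs and
#' TEPs; sham pulses share the artifact model (pulse spike and exponential
#' decay on all channels) but evoke no motor or cortical response. HEP
#' deflections ride on every heartbeat, with amplitude coupled to the
#' standardised MEP noise draw of a same-cycle late (>= 400 ms post-R)
#' real pulse.
#'
#' @param cfg A `synth_config`.
#' @return List with `recording`, `events` and `truth` (beat schedule,
#'   per-trial table and the echoed config).
#' @export
gen_session <- function(cfg) {
  set.seed(cfg$seed)
  isi <- function(n) stats::runif(n, cfg$isi_range_s[1], cfg$isi_range_s[2])
  tms_times <- 5 + cumsum(isi(cfg$n_tms))
  gap <- if (cfg$n_sham > 0) 5 else 0
  sham_times <- if (cfg$n_sham > 0)
    max(tms_times, 4) + gap + cumsum(isi(cfg$n_sham)) else numeric(0)
  duration_s <- max(c(tms_times, sham_times, 30)) + 5
  n_samp <- round(duration_s * cfg$rate)

  # beats need systolic-pulse times; true systole depends on the beat being
  # generated, so build beats with the pulse list and classify afterwards
  beats <- .gen_beats(cfg, duration_s, tms_times = tms_times)
  ecg <- .ecg_trace(beats, cfg$rate, n_samp, cfg$noise_sd$ecg)

  all_onsets <- c(tms_times, sham_times)
  all_cond <- c(rep("tms", cfg$n_tms), rep("sham", cfg$n_sham))
  info <- lapply(all_onsets, .true_phase, beats = beats)
  phase <- vapply(info, `[[`, "", "phase")
  dist_ms <- vapply(info, function(z) as.numeric(z$distance_ms), 1)
  beat_idx <- vapply(info, function(z) as.integer(z$beat), 1L)

  z <- stats::rnorm(length(all_onsets))
  log_amp <- log(cfg$mep_base_uv) -
    cfg$mep_distance_slope * dist_ms +
    log(cfg$mep_systole_gain) * (phase == "systole") +
    cfg$mep_log_noise_sd * z
  true_mep <- ifelse(all_cond == "tms", exp(log_amp), 0)
  true_mep[is.na(true_mep)] <- 0

  chs <- c(cfg$eeg_channels, "ECG", "EMG")
  roles <- infer_roles(chs)
  data <- matrix(0, length(chs), n_samp, dimnames = list(chs, NULL))
  eeg_idx <- which(roles == "eeg")
  for (i in eeg_idx) data[i, ] <- stats::rnorm(n_samp, 0, cfg$noise_sd$eeg)
  data["ECG", ] <- ecg
  emg <- stats::rnorm(n_samp, 0, cfg$noise_sd$emg)

  mep_sh <- .mep_shape(cfg$rate)
  for (j in seq_along(all_onsets)) {
    if (all_cond[j] != "tms" || is.na(true_mep[j]) || true_mep[j] <= 0) next
    start <- round((all_onsets[j] + 0.020) * cfg$rate) + 1
    emg <- .add_at(emg, start, mep_sh * true_mep[j])
  }
  data["EMG", ] <- emg

  # TEP deflection on hotspot channels (real pulses only)
  hotspot <- intersect(c("C4", "CP4", "C6", "CP6"), chs)
  tep_t <- seq(cfg$tep_window_ms[1], cfg$tep_window_ms[2]) / 1000
  tep_center <- mean(cfg$tep_window_ms) / 1000
  tep_n <- round(diff(cfg$tep_window_ms) / 1000 * cfg$rate)
  tep_tt <- seq(0, diff(cfg$tep_window_ms) / 1000, length.out = tep_n)
  tep_shape <- exp(-((tep_tt - diff(cfg$tep_window_ms) / 2000)^2) /
                     (2 * (diff(cfg$tep_window_ms) / 6000)^2))
  for (j in seq_along(all_onsets)) {
    if (all_cond[j] != "tms") next
    amp <- cfg$tep_amp_uv * if (!is.na(phase[j]) && phase[j] == "systole")
      cfg$tep_systole_gain else 1
    start <- round((all_onsets[j] + cfg$tep_window_ms[1] / 1000) * cfg$rate) + 1
    for (ch in hotspot)
      data[ch, ] <- .add_at(data[ch, ], start, tep_shape * amp)
  }

  # HEP on centroparietal channels, every beat; amplitude coupled to the
  # MEP noise draw of a same-cycle late real pulse when one exists
  cp <- intersect(c("FC2", "Cz", "C4", "CP1", "CP2", "Pz", "P4", "C1", "C2",
                    "CPz", "CP4", "P1", "P2"), chs)
  hep_n <- round(diff(cfg$hep_window_ms) / 1000 * cfg$rate)
  hep_tt <- seq_len(hep_n) / cfg$rate
  hep_shape <- sin(pi * seq(0, 1, length.out = hep_n))^2
  hep_amp_beat <- rep(cfg$hep_amp_uv, nrow(beats))
  late <- which(all_cond == "tms" & !is.na(dist_ms) & dist_ms >= 400)
  for (j in late)
    hep_amp_beat[beat_idx[j]] <- cfg$hep_amp_uv + cfg$hep_mep_coupling * z[j]
  for (k in seq_len(nrow(beats))) {
    start <- round((beats$r_time[k] + cfg$hep_window_ms[1] / 1000) * cfg$rate) + 1
    for (ch in cp)
      data[ch, ] <- .add_at(data[ch, ], start, hep_shape * hep_amp_beat[k])
  }

  # TMS artifacts on every channel, real and sham alike
  dec_n <- round(0.3 * cfg$rate)
  dec_shape <- exp(-(seq_len(dec_n) / cfg$rate) / (cfg$decay_tau_ms / 1000))
  pw <- max(1, round(cfg$pulse_width_ms / 1000 * cfg$rate))
  ch_gain <- stats::runif(length(chs), 0.5, 1.5)
  for (j in seq_along(all_onsets)) {
    start <- round(all_onsets[j] * cfg$rate) + 1
    for (i in seq_along(chs)) {
      data[i, ] <- .add_at(data[i, ], start,
                           rep(cfg$pulse_amp_uv * ch_gain[i], pw))
      data[i, ] <- .add_at(data[i, ], start + pw,
                           dec_shape * cfg$decay_amp_uv * ch_gain[i])
    }
  }

  rec <- recording(data, rate = cfg$rate, channels = chs, roles = roles,
                   montage = standard_montage(cfg$eeg_channels))
  ev <- event_list(onset_s = all_onsets, label = all_cond)
  trials <- data.frame(onset_s = all_onsets, condition = all_cond,
                       true_phase = phase, distance_ms = dist_ms,
                       beat = beat_idx, true_mep_uv = true_mep, z = z)
  trials <- trials[order(trials$onset_s), ]
  rownames(trials) <- NULL
  list(recording = rec, events = ev,
       truth = list(beats = beats, trials = trials, config = cfg))
}

#' Generate a synthetic pinch motor task session
#'
#' EMG bursts with a shaped rise at the true onsets (force scaled by
#' `erd_systole_gain` for systolic onsets) and an ongoing 8-25 Hz
#' sensorimotor oscillation on the hotspot channels whose power drops by
#' `erd_depth` (deeper for systolic onsets) for ~700 ms after each onset.
#'
#' @param cfg A `synth_config`.
#' @param rest Logical: if `TRUE`, generate the resting-state control
#'   (beats and ongoing oscillation, no bursts, no ERD).
#' @return List with `recording`, `events` and `truth`.
#' @export
gen_pinch_task <- function(cfg, rest = FALSE) {
  set.seed(cfg$seed + 7L)
  n_tr <- if (rest) 0 else cfg$n_pinch
  duration_s <- max(30, n_tr * 6 + 10)
  n_samp <- round(duration_s * cfg$rate)
  beats <- .gen_beats(cfg, duration_s)
  ecg <- .ecg_trace(beats, cfg$rate, n_samp, cfg$noise_sd$ecg)

  onsets <- if (n_tr > 0) 5 + (seq_len(n_tr) - 1) * 6 + stats::runif(n_tr, 0, 1)
            else numeric(0)
  info <- lapply(onsets, .true_phase, beats = beats)
  phase <- vapply(info, `[[`, "", "phase")

  chs <- c(cfg$eeg_channels, "ECG", "EMG")
  roles <- infer_roles(chs)
  data <- matrix(0, length(chs), n_samp, dimnames = list(chs, NULL))
  eeg_idx <- which(roles == "eeg")
  for (i in eeg_idx) data[i, ] <- stats::rnorm(n_samp, 0, cfg$noise_sd$eeg)
  data["ECG", ] <- ecg

  tt <- (seq_len(n_samp) - 1) / cfg$rate
  # ongoing sensorimotor rhythm with post-onset amplitude suppression
  sm <- intersect(c("C4", "CP4", "C6", "CP6"), chs)
  supp <- rep(1, n_samp)
  for (j in seq_along(onsets)) {
    d_eff <- min(cfg$erd_depth *
                   if (phase[j] == "systole") cfg$erd_systole_gain else 1, 0.95)
    idx <- which(tt >= onsets[j] & tt <= onsets[j] + 0.7)
    supp[idx] <- sqrt(1 - d_eff)
  }
  for (ch in sm) {
    ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
    osc <- cfg$osc_amp_uv * (sin(2 * pi * 10 * tt + ph1) +
                             0.6 * sin(2 * pi * 20 * tt + ph2))
    data[ch, ] <- data[ch, ] + osc * supp
  }

  # EMG: baseline noise plus shaped contraction bursts (band-limited noise)
  emg <- stats::rnorm(n_samp, 0, cfg$noise_sd$emg)
  if (n_tr > 0) {
    bp <- signal::butter(4, c(20, min(450, cfg$rate / 2 * 0.9)) / (cfg$rate / 2),
                         type = "pass")
    burst_len <- round(2.5 * cfg$rate)
    env_t <- seq_len(burst_len) / cfg$rate
    env <- pmin(env_t / 0.15, 1) * pmin(pmax((2.5 - env_t) / 0.3, 0), 1)
    for (j in seq_along(onsets)) {
      gain <- 60 * if (phase[j] == "systole") cfg$erd_systole_gain else 1
      carrier <- signal::filtfilt(bp, stats::rnorm(burst_len, 0, 1))
      emg <- .add_at(emg, round(onsets[j] * cfg$rate) + 1, carrier * env * gain)
    }
  }
  data["EMG", ] <- emg

  rec <- recording(data, rate = cfg$rate, channels = chs, roles = roles,
                   montage = standard_montage(cfg$eeg_channels))
  ev <- if (n_tr > 0) event_list(onset_s = onsets, label = "pinch_on")
        else event_list(onset_s = numeric(0), label = character(0))
  list(recording = rec, events = ev,
       truth = list(beats = beats,
                    trials = data.frame(onset_s = onsets, true_phase = phase),
                    config = cfg))
}

#' Trial-statistics layer of the generator
#'
#' Simulates the per-trial statistical model of a session (true phases,
#' distances from R, log-MEP draws and interbeat-interval triplets)
#' without synthesising waveforms. This is the same generative model as
#' [gen_session()] restricted to its trial-level quantities, and is what
#' calibration and power studies over many replicate sessions use.
#'
#' @param cfg A `synth_config`.
#' @param n_participants Number of independent participants to simulate;
#'   participant p uses seed `cfg$seed + p`.
#' @return data.frame with one row per real-TMS trial: `participant`,
#'   `phase`, `distance_ms`, `mep_uv`, `ibi_pre`, `ibi_tms`, `ibi_post` (ms).
#' @export
gen_trial_stats <- function(cfg, n_participants = 1) {
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    set.seed((cfg$seed + p) %% .Machine$integer.max)
    tms_times <- 5 + cumsum(stats::runif(cfg$n_tms, cfg$isi_range_s[1],
                                         cfg$isi_range_s[2]))
    duration_s <- max(tms_times) + 5
    beats <- .gen_beats(cfg, duration_s, tms_times = tms_times)
    info <- lapply(tms_times, .true_phase, beats = beats)
    phase <- vapply(info, `[[`, "", "phase")
    dist_ms <- vapply(info, function(z) as.numeric(z$distance_ms), 1)
    beat_idx <- vapply(info, function(z) as.integer(z$beat), 1L)
    z <- stats::rnorm(length(tms_times))
    mep <- exp(log(cfg$mep_base_uv) - cfg$mep_distance_slope * dist_ms +
                 log(cfg$mep_systole_gain) * (phase == "systole") +
                 cfg$mep_log_noise_sd * z)
    ok <- beat_idx >= 2 & beat_idx <= nrow(beats) - 1
    out[[p]] <- data.frame(
      participant = p, phase = phase, distance_ms = dist_ms, mep_uv = mep,
      ibi_pre = ifelse(ok, beats$rr[pmax(beat_idx - 1, 1)] * 1000, NA),
      ibi_tms = beats$rr[beat_idx] * 1000,
      ibi_post = ifelse(ok, beats$rr[pmin(beat_idx + 1, nrow(beats))] * 1000, NA))
  }
  do.call(rbind, out)
}
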