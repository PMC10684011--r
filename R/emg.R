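#' Peak-to-peak MEP amplitude
#'
#' Baseline-corrects a single-trial EMG trace with the mean of the
#' prestimulus window (default -110 to -10 ms) and returns max - min in
#' the response window (default 20 to 40 ms post-stimulus).
#'
#' @param trace Numeric vector (one trial, one channel).
#' @param times Time axis in seconds relative to the stimulus.
#' @param baseline,window `c(start, end)` windows in seconds.
#' @return Amplitude in the trace's units (nonnegative).
#' @export
mep_amplitude <- function(trace, times, baseline = c(-0.110, -0.010),
                          window = c(0.020, 0.040)) {
  bsel <- times >= baseline[1] & times <= baseline[2]
  wsel <- times >= window[1] & times <= window[2]
  if (!any(bsel) || !any(wsel)) stop("baseline or response window outside epoch")
  v <- trace - mean(trace[bsel])
  max(v[wsel]) - min(v[wsel])
}

#' MEP amplitudes for all trials of an epochs object
#'
#' @param ep `epochs` locked to the stimulation, containing an EMG channel.
#' @param channel EMG channel label (default: first emg-role channel).
#' @inheritParams mep_amplitude
#' @return Numeric vector, one amplitude per trial.
#' @export
mep_amplitudes <- function(ep, channel = NULL, baseline = c(-0.110, -0.010),
                           window = c(0.020, 0.040)) {
  if (is.null(channel)) channel <- ep$channels[ep$roles == "emg"][1]
  j <- match(channel, ep$channels)
  if (is.na(j)) stop("EMG channel not found: ", channel)
  vapply(seq_len(dim(ep$data)[1]), function(i)
    mep_amplitude(ep$data[i, j, ], ep$times, baseline, window), numeric(1))
}

#' Validity filtering of TMS and sham trials
#'
#' A real TMS trial is valid iff its MEP exceeds 50 uV (a successful
#' stimulation must evoke a response); a sham trial is valid iff its
#' amplitude is at most 50 uV (a successful sham must not).
#'
#' @param records data.frame with columns `amplitude` (uV) and `condition`
#'   (`"tms"` or `"sham"`).
#' @param threshold_uv Validity threshold.
#' @return `records` with a logical `valid` column.
#' @export
validate_trials <- function(records, threshold_uv = 50) {
  stopifnot(all(c("amplitude", "condition") %in% names(records)))
  records$valid <- ifelse(records$condition == "tms",
                          records$amplitude > threshold_uv,
                          records$amplitude <= threshold_uv)
  records
}

#' Linear EMG envelope
#'
#' Band-pass (default 10-500 Hz) + notch filtering, full-wave
#' rectification and an 8 Hz zero-phase low-pass.
#'
#' @param x Numeric vector.
#' @param rate Sampling rate (> 1000 Hz for the default band).
#' @param band,notch Band-pass and notch edges in Hz.
#' @param lp Low-pass cut-off for the envelope, Hz.
#' @return Envelope, same length (nonnegative up to filter ringing,
#'   clipped at 0).
#' @export
emg_envelope <- function(x, rate, band = c(10, 500), notch = c(45, 55),
                         lp = 8) {
  nyq <- rate / 2
  if (max(band) >= nyq) stop("band edge at or above Nyquist")
  bp <- signal::butter(4, band / nyq, type = "pass")
  ns <- signal::butter(4, notch / nyq, type = "stop")
  lpf <- signal::butter(4, lp / nyq, type = "low")
  v <- signal::filtfilt(ns, signal::filtfilt(bp, x))
  env <- signal::filtfilt(lpf, abs(v))
  pmax(env, 0)
}

#' Teager-Kaiser energy operator
#'
#' `psi(n) = x(n)^2 - x(n-1) * x(n+1)`; endpoints are zero.
#'
#' @param x Numeric vector.
#' @return Numeric vector, same length.
#' @export
tke <- function(x) {
  n <- length(x)
  psi <- numeric(n)
  if (n >= 3) psi[2:(n - 1)] <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  psi
}

#' Movement onset from the Teager-Kaiser energy
#'
#' The TKE of the (optionally band-passed) trace is compared to a
#' baseline-derived threshold (baseline mean + k * SD); the onset is the
#' first crossing sustained for at least `sustain_s`. Trials with no
#' sustained crossing return `NA` with a review flag.
#'
#' @param x Numeric vector (one trial).
#' @param times Time axis, seconds relative to the candidate movement;
#'   `baseline` must precede activity.
#' @param rate Sampling rate, Hz.
#' @param baseline `c(start, end)` baseline window, seconds.
#' @param k Threshold multiplier on the baseline TKE SD.
#' @param sustain_s Minimum supra-threshold duration.
#' @param smooth_s TKE smoothing window (moving average), seconds.
#' @return List: `onset` (seconds, or `NA`), `flagged` (logical).
#' @export
tke_onset <- function(x, times, rate, baseline = c(-1, -0.1), k = 8,
                      sustain_s = 0.025, smooth_s = 0.01) {
  psi <- tke(x)
  w <- max(1, round(smooth_s * rate))
  psi <- as.numeric(stats::filter(psi, rep(1 / w, w), sides = 2))
  psi[is.na(psi)] <- 0
  bsel <- times >= baseline[1] & times <= baseline[2]
  if (!any(bsel)) stop("baseline window outside trace")
  thr <- mean(psi[bsel]) + k * stats::sd(psi[bsel])
  if (!is.finite(thr)) thr <- 0
  need <- max(1, round(sustain_s * rate))
  above <- psi > thr
  above[bsel] <- FALSE
  runs <- rle(above)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= need)
  if (length(hit) == 0) return(list(onset = NA_real_, flagged = TRUE))
  list(onset = times[starts[hit[1]]], flagged = FALSE)
}

#' Sham-correct phase-wise EMG summaries
#'
#' Subtracts the sham-condition mean (trace or scalar) from the real
#' condition, per phase cell.
#'
#' @param real,sham Named lists (one element per phase) of numeric
#'   vectors/scalars: per-phase mean traces or amplitudes.
#' @return Named list of corrected values.
#' @export
sham_emg_correct <- function(real, sham) {
  out <- real
  for (ph in names(real)) {
    if (is.null(sham[[ph]])) stop("empty sham phase cell: ", ph)
    out[[ph]] <- real[[ph]] - sham[[ph]]
  }
  out
}

#' Phase-matched pseudo-events from a resting recording
#'
#' Draws pseudo-event times uniformly inside the systole and diastole
#' windows of a resting-state cardiac map (at most one event per beat per
#' phase), for running the envelope/ERD pipelines as a no-stimulation
#' control.
#'
#' @param map A `cardiac_map` of the resting recording.
#' @param n Number of pseudo-events requested per phase.
#' @param seed RNG seed (reproducible picks).
#' @return `event_list` with labels `"rest_probe"` and a `phase` column;
#'   `attr(., "n_requested")` records the request when beats run short.
#' @export
rest_control_sampling <- function(map, n, seed = 1) {
  usable <- which(map$usable)
  if (length(usable) == 0) stop("no usable beats in resting cardiac map")
  set.seed(seed)
  n_eff <- min(n, length(usable))
  beats <- sample(usable, n_eff)
  sys_t <- map$r_time[beats] + stats::runif(n_eff) * map$sys_len[beats]
  dia_t <- map$dia_start[beats] + stats::runif(n_eff) * map$sys_len[beats]
  ev <- event_list(onset_s = c(sys_t, dia_t),
                   label = rep("rest_probe", 2 * n_eff),
                   phase = rep(c("systole", "diastole"), each = n_eff))
  attr(ev, "n_requested") <- n
  ev
}
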