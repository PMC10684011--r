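#' Heartbeat-evoked potential analysis configuration
#'
#' @param min_r_to_tms_s Minimum distance from the preceding R-peak for a
#'   TMS trial to enter the HEP analysis (keeps the HEP window free of
#'   stimulation activity).
#' @param epoch_s Epoch window around the R-peak.
#' @param baseline_s Baseline window relative to the R-peak.
#' @param n_shuffles Distance-shuffling repetitions for the mock-event
#'   artifact estimate.
#' @param electrodes Centroparietal cluster tested.
#' @param test_window_s Prestimulus HEP test window (s post-R).
#' @param n_bins MEP-amplitude bins per participant.
#' @return A `hep_config` list.
#' @export
hep_config <- function(min_r_to_tms_s = 0.400, epoch_s = c(-0.100, 0.400),
                       baseline_s = c(-0.100, 0), n_shuffles = 10,
                       electrodes = c("FC2", "Cz", "C4", "CP1", "CP2", "Pz",
                                      "P4", "C1", "C2", "CPz", "CP4", "P1",
                                      "P2"),
                       test_window_s = c(0.296, 0.400), n_bins = 3) {
  stopifnot(test_window_s[1] >= epoch_s[1], test_window_s[2] <= epoch_s[2],
            n_bins >= 2)
  structure(as.list(environment()), class = "hep_config")
}

#' Select TMS trials far enough from the preceding R-peak
#'
#' @param classified Output of [classify_events()] for the TMS events.
#' @param cfg A `hep_config`.
#' @return List: `keep` (row indices), `distances_s` (kept R-to-TMS
#'   distances, seconds; the input of the mock-event construction).
#' @export
select_late_tms_trials <- function(classified, cfg = hep_config()) {
  d <- classified$distance_ms / 1000
  keep <- which(!is.na(d) & d >= cfg$min_r_to_tms_s)
  if (length(keep) == 0) {
    h <- stats::quantile(d, na.rm = TRUE)
    stop("no TMS trials at least ", cfg$min_r_to_tms_s * 1000,
         " ms after the preceding R-peak; distance quantiles (ms): ",
         paste(round(h * 1000), collapse = ", "))
  }
  list(keep = keep, distances_s = d[keep])
}

#' Mock-event estimate of the TMS artifact in the HEP window
#'
#' The R-to-TMS distances of the kept trials are shuffled `n_shuffles`
#' times; each shuffle places a mock event at (TMS latency - shuffled
#' distance). Epochs around all mock events are averaged across events
#' and shuffles, yielding a template of whatever is strictly TMS-locked
#' inside the heartbeat-evoked response window. Mock epochs outside the
#' recording are dropped and counted.
#'
#' @param rec `recording` (EEG channels are used).
#' @param tms_times Kept TMS latencies, seconds.
#' @param distances_s Matching R-to-TMS distances, seconds.
#' @param cfg A `hep_config`.
#' @param seed RNG seed (fixed seed reproduces the template exactly).
#' @param channels Channel subset (default: all EEG channels).
#' @return List: `template` (channels x time matrix), `times`,
#'   `n_dropped`, `channels`.
#' @export
estimate_mock_artifact <- function(rec, tms_times, distances_s,
                                   cfg = hep_config(), seed = 1,
                                   channels = NULL) {
  stopifnot(length(tms_times) == length(distances_s), length(tms_times) >= 2)
  if (is.null(channels)) channels <- rec$channels[rec$roles == "eeg"]
  set.seed(seed)
  n_t <- round(diff(cfg$epoch_s) * rec$rate) + 1
  times <- cfg$epoch_s[1] + (seq_len(n_t) - 1) / rec$rate
  acc <- matrix(0, length(channels), n_t)
  n_used <- 0; n_dropped <- 0
  n_samp <- ncol(rec$data)
  chd <- rec$data[channels, , drop = FALSE]
  for (s in seq_len(cfg$n_shuffles)) {
    mock <- tms_times - sample(distances_s)
    for (t0 in mock) {
      lo <- round((t0 + cfg$epoch_s[1]) * rec$rate) + 1
      hi <- lo + n_t - 1
      if (lo < 1 || hi > n_samp) { n_dropped <- n_dropped + 1; next }
      acc <- acc + chd[, lo:hi, drop = FALSE]
      n_used <- n_used + 1
    }
  }
  if (n_used == 0) stop("all mock epochs fell outside the recording")
  list(template = acc / n_used, times = times, n_dropped = n_dropped,
       channels = channels)
}

#' Extract heartbeat-evoked potentials
#'
#' Epochs locked to the R-peaks preceding the kept TMS trials, with the
#' mock-event artifact template subtracted and the prestimulus baseline
#' removed.
#'
#' @param rec `recording`.
#' @param r_times R-peak times to lock to (one per kept trial), seconds.
#' @param template Output of [estimate_mock_artifact()], or `NULL` for a
#'   plain R-locked ERP.
#' @param cfg A `hep_config`.
#' @return `epochs` over the template's channels.
#' @export
extract_hep <- function(rec, r_times, template = NULL, cfg = hep_config()) {
  channels <- if (!is.null(template)) template$channels
              else rec$channels[rec$roles == "eeg"]
  ev <- event_list(onset_s = r_times, label = "rpeak")
  ep <- epoch(rec, ev, "rpeak", cfg$epoch_s[1], cfg$epoch_s[2],
              channels = channels)
  if (!is.null(template)) {
    stopifnot(ncol(template$template) == length(ep$times))
    for (i in seq_len(dim(ep$data)[1]))
      ep$data[i, , ] <- ep$data[i, , ] - template$template
    ep$provenance <- c(ep$provenance, list(list(stage = "mock_template_subtraction")))
  }
  baseline_correct(ep, cfg$baseline_s)
}

#' Bin trials by MEP amplitude
#'
#' Sorts trials ascending by amplitude and splits them into `n_bins`
#' contiguous near-equal groups, any remainder going to the lower bins.
#' Ties keep the original trial order (stable sort).
#'
#' @param amplitudes Numeric vector of MEP amplitudes.
#' @param n_bins Number of bins.
#' @return Integer vector of bin labels (1 = weakest) aligned to the
#'   input order.
#' @export
bin_by_mep <- function(amplitudes, n_bins = 3) {
  n <- length(amplitudes)
  if (n < n_bins) stop("fewer trials (", n, ") than bins (", n_bins, ")")
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ord <- order(amplitudes)                        # stable: ties by index
  labels <- integer(n)
  labels[ord] <- rep(seq_len(n_bins), times = sizes)
  labels
}

#' Strong-versus-weak HEP contrast, and trial-selection variants
#'
#' Computes per-bin mean HEP waveforms over the configured centroparietal
#' electrodes and the strong-minus-weak (last vs first bin) contrast in
#' the test window. `variant` chooses the trial-selection rule:
#' `"same_cycle"` (default; late TMS trials, HEP of the same cycle),
#' `"previous_cycle"` (early TMS trials, HEP locked to the R-peak of the
#' preceding cycle) and `"rest"` takes precomputed rest-locked epochs for
#' comparison against TMS-block HEPs.
#'
#' @param ep `epochs` from [extract_hep()].
#' @param amplitudes Per-trial MEP amplitudes aligned with `ep`.
#' @param cfg A `hep_config`.
#' @param variant Label recorded in the output.
#' @return List: `times` (test window), `bin_means` (bins x time),
#'   `contrast` (strong - weak trace), `bins` (per-trial labels),
#'   `trial_window_means` (trials x 1 window-mean per trial), `variant`.
#' @export
hep_bin_contrast <- function(ep, amplitudes, cfg = hep_config(),
                             variant = "same_cycle") {
  stopifnot(length(amplitudes) == dim(ep$data)[1])
  bins <- bin_by_mep(amplitudes, cfg$n_bins)
  el <- intersect(cfg$electrodes, ep$channels)
  if (length(el) == 0) stop("no configured electrodes present")
  jj <- match(el, ep$channels)
  sel_t <- ep$times >= cfg$test_window_s[1] & ep$times <= cfg$test_window_s[2] &
    !ep$mask
  cluster_trace <- apply(ep$data[, jj, sel_t, drop = FALSE], c(1, 3), mean)
  bin_means <- t(vapply(seq_len(cfg$n_bins), function(b)
    colMeans(cluster_trace[bins == b, , drop = FALSE]),
    numeric(sum(sel_t))))
  list(times = ep$times[sel_t], bin_means = bin_means,
       contrast = bin_means[cfg$n_bins, ] - bin_means[1, ],
       bins = bins, trial_window_means = rowMeans(cluster_trace),
       variant = variant)
}
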