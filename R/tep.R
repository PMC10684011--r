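#' TMS-EEG cleaning pipeline configuration
#'
#' Windows and parameters for the artifact-cleaning pipeline applied
#' before TMS-evoked potential (TEP) extraction: epoching, baseline,
#' pulse-sample excision, decay-component ICA, filtering, cubic
#' interpolation, mastoid re-referencing and downsampling.
#'
#' @param epoch_s Epoch window around the pulse, seconds.
#' @param baseline_s Prestimulus baseline window.
#' @param cut1_s Pulse window excised before the first ICA.
#' @param decay_window_s Window in which component variance ranks decay
#'   artifacts.
#' @param n_decay_components Components removed in ICA round 1.
#' @param band,notch Filter edges, Hz.
#' @param interp_s Window replaced by cubic interpolation (flagged and
#'   excluded from statistics).
#' @param hotspot Electrode cluster over the stimulated motor cortex.
#' @param tep_window_s Early-TEP evaluation window.
#' @param target_rate Final sampling rate, Hz.
#' @param mastoids Reference channel labels.
#' @return A `tep_config` list.
#' @export
tep_config <- function(epoch_s = c(-1.4, 1.0), baseline_s = c(-0.110, -0.010),
                       cut1_s = c(-0.002, 0.008), decay_window_s = c(-0.150, 0.150),
                       n_decay_components = 3, band = c(0.5, 45),
                       notch = c(45, 55), interp_s = c(-0.002, 0.015),
                       hotspot = c("C4", "CP4", "C6", "CP6"),
                       tep_window_s = c(0.015, 0.060), target_rate = 500,
                       mastoids = c("M1", "M2")) {
  stopifnot(cut1_s[1] >= interp_s[1], cut1_s[2] <= interp_s[2],
            interp_s[1] >= epoch_s[1], interp_s[2] <= epoch_s[2])
  structure(as.list(environment()), class = "tep_config")
}

# concatenate epochs into channels x (trials * kept samples), excluding
# masked samples and an extra exclusion window
.concat_epochs <- function(ep, exclude_s = NULL) {
  keep <- !ep$mask
  if (!is.null(exclude_s))
    keep <- keep & !(ep$times >= exclude_s[1] & ep$times <= exclude_s[2])
  d <- ep$data[, , keep, drop = FALSE]
  dm <- dim(d)
  # -> channels x (time * trials)
  m <- matrix(aperm(d, c(2, 3, 1)), dm[2], dm[1] * dm[3])
  list(m = m, keep = keep, n_trials = dm[1])
}

.unconcat_epochs <- function(ep, m, keep) {
  d <- ep$data
  n_keep <- sum(keep)
  arr <- array(m, c(nrow(m), n_keep, dim(d)[1]))
  for (i in seq_len(dim(d)[1])) d[i, , keep] <- arr[, , i]
  ep$data <- d
  ep
}

#' Remove TMS decay components by ICA
#'
#' Decomposes the concatenated epochs (pulse samples excluded) with ICA,
#' ranks components by the variance they explain inside the decay window,
#' zeroes the top `n_decay_components` and back-projects the remainder.
#'
#' @param ep `epochs` (EEG channels only are decomposed).
#' @param cfg A `tep_config`.
#' @param seed ICA seed (component selection is deterministic given it).
#' @return List: `epochs` (cleaned), `removed` (component indices),
#'   `var_explained` (per component, in the decay window).
#' @export
remove_decay_components <- function(ep, cfg = tep_config(), seed = 1) {
  if (cfg$n_decay_components == 0)
    return(list(epochs = ep, removed = integer(0), var_explained = numeric(0)))
  eeg <- which(ep$roles == "eeg")
  cc <- .concat_epochs(ep)
  ica <- fast_ica(cc$m[eeg, , drop = FALSE], seed = seed)
  # variance each component explains inside the decay window
  win <- ep$times[cc$keep] >= cfg$decay_window_s[1] &
         ep$times[cc$keep] <= cfg$decay_window_s[2]
  win_full <- rep(win, times = cc$n_trials)
  ve <- vapply(seq_len(nrow(ica$S)), function(c_) {
    sum(ica$A[, c_]^2) * stats::var(ica$S[c_, win_full])
  }, numeric(1))
  removed <- order(ve, decreasing = TRUE)[seq_len(min(cfg$n_decay_components,
                                                      length(ve)))]
  keep_c <- setdiff(seq_len(nrow(ica$S)), removed)
  clean <- ica$A[, keep_c, drop = FALSE] %*% ica$S[keep_c, , drop = FALSE] +
    ica$center
  m <- cc$m
  m[eeg, ] <- clean
  ep <- .unconcat_epochs(ep, m, cc$keep)
  ep$provenance <- c(ep$provenance,
                     list(list(stage = "ica_decay_removal", removed = removed,
                               var_explained = ve, seed = seed)))
  list(epochs = ep, removed = removed, var_explained = ve)
}

# rule-based classification of residual artifact components: strong ECG
# correlation, frontal (ocular) topography concentration, or
# high-frequency (muscle) spectral dominance
.classify_artifact_components <- function(ica, channels, rate,
                                          ecg_trace = NULL,
                                          ecg_cor = 0.7, frontal_frac = 0.6,
                                          hf_frac = 0.6) {
  n_comp <- nrow(ica$S)
  frontal <- grepl("^(Fp|AF)", channels)
  flag <- logical(n_comp)
  for (c_ in seq_len(n_comp)) {
    if (!is.null(ecg_trace) &&
        abs(stats::cor(ica$S[c_, ], ecg_trace)) > ecg_cor) { flag[c_] <- TRUE; next }
    a2 <- ica$A[, c_]^2
    if (any(frontal) && sum(a2[frontal]) / sum(a2) > frontal_frac) {
      flag[c_] <- TRUE; next
    }
    sp <- stats::spec.pgram(ica$S[c_, ], plot = FALSE, taper = 0)
    hf <- sp$freq * rate > 30
    if (mean(hf) > 0 && sum(sp$spec[hf]) / sum(sp$spec) > hf_frac) flag[c_] <- TRUE
  }
  which(flag)
}

#' Cubic interpolation over the stimulus window of epochs
#'
#' Replaces samples inside `window_s` (per trial and channel) by a cubic
#' spline fitted on flanking samples, and flags them in the exclusion
#' mask so they never enter statistics.
#'
#' @param ep `epochs`.
#' @param window_s `c(start, end)` seconds relative to the lock event.
#' @param flank_s Flanking context per side.
#' @export
interpolate_epochs <- function(ep, window_s, flank_s = 0.02) {
  sel <- which(ep$times >= window_s[1] & ep$times <= window_s[2])
  if (length(sel) == 0) return(ep)
  fl <- max(4, round(flank_s * ep$rate))
  ctx <- setdiff(c(seq(min(sel) - fl, min(sel) - 1),
                   seq(max(sel) + 1, max(sel) + fl)),
                 c(sel, seq_len(0)))
  ctx <- ctx[ctx >= 1 & ctx <= length(ep$times)]
  d <- dim(ep$data)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    ep$data[i, j, sel] <- stats::spline(ep$times[ctx], ep$data[i, j, ctx],
                                        xout = ep$times[sel],
                                        method = "natural")$y
  ep$mask[sel] <- TRUE
  ep$provenance <- c(ep$provenance,
                     list(list(stage = "interpolate", window = window_s)))
  ep
}

#' Run the full TMS-EEG cleaning pipeline
#'
#' Stage order: epoch -> baseline -> excise pulse samples and concatenate
#' -> ICA round 1 (decay components removed, unfiltered copy kept) ->
#' band-pass + notch -> ICA round 2 (rule-based artifact classification,
#' manual override honored; weights applied to the unfiltered copy) ->
#' cubic interpolation over the stimulus window (samples flagged and
#' excluded from statistics) -> band-pass + notch -> mastoid
#' re-referencing -> downsampling. Every stage is logged with its
#' parameters in the output's provenance.
#'
#' @param raw A `recording` at the acquisition rate, mastoids present.
#' @param events An `event_list`.
#' @param label Event label to lock to (e.g. `"tms"` or `"sham"`).
#' @param cfg A `tep_config`.
#' @param seed ICA seed.
#' @param manual_remove Optional integer indices of round-2 components to
#'   remove instead of the rule-based selection.
#' @return `epochs` at `cfg$target_rate` with provenance and exclusion
#'   mask.
#' @export
run_tep_pipeline <- function(raw, events, label = "tms", cfg = tep_config(),
                             seed = 1, manual_remove = NULL) {
  if (inherits(raw, "epochs")) {
    warning("input already carries pipeline provenance; stages not re-applied")
    return(raw)
  }
  run_stage <- function(expr, stage) {
    tryCatch(expr, error = function(e)
      stop("TEP pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE))
  }
  keep_ch <- raw$channels[raw$roles %in% c("eeg", "ecg")]
  ep <- run_stage(epoch(raw, events, label, cfg$epoch_s[1], cfg$epoch_s[2],
                        baseline_window = cfg$baseline_s, channels = keep_ch),
                  "epoch")
  # excise pulse samples before any decomposition
  ep$mask <- ep$times >= cfg$cut1_s[1] & ep$times <= cfg$cut1_s[2]
  ep$provenance <- c(ep$provenance, list(list(stage = "cut_pulse",
                                              window = cfg$cut1_s)))
  r1 <- run_stage(remove_decay_components(ep, cfg, seed = seed), "ica_decay")
  unfiltered <- r1$epochs
  filt <- run_stage(bandpass_notch(unfiltered, cfg$band, cfg$notch,
                                   roles = "eeg"), "filter_1")
  # round 2: decompose the filtered data, remove on the unfiltered copy
  eeg <- which(filt$roles == "eeg")
  cc_f <- .concat_epochs(filt)
  ica2 <- run_stage(fast_ica(cc_f$m[eeg, , drop = FALSE], seed = seed + 100),
                    "ica_round2")
  ecg_row <- which(filt$roles == "ecg")[1]
  ecg_trace <- if (!is.na(ecg_row)) cc_f$m[ecg_row, ] else NULL
  removed2 <- if (!is.null(manual_remove)) manual_remove
              else .classify_artifact_components(ica2, filt$channels[eeg],
                                                 filt$rate, ecg_trace)
  cc_u <- .concat_epochs(unfiltered)
  src_u <- ica2$W %*% (cc_u$m[eeg, , drop = FALSE] -
                         rowMeans(cc_u$m[eeg, , drop = FALSE]))
  keep_c <- setdiff(seq_len(nrow(src_u)), removed2)
  cc_u$m[eeg, ] <- ica2$A[, keep_c, drop = FALSE] %*%
    src_u[keep_c, , drop = FALSE] + rowMeans(cc_u$m[eeg, , drop = FALSE])
  ep2 <- .unconcat_epochs(unfiltered, cc_u$m, cc_u$keep)
  ep2$provenance <- c(ep2$provenance,
                      list(list(stage = "ica_artifact_removal",
                                removed = removed2,
                                manual = !is.null(manual_remove))))
  ep2 <- run_stage(interpolate_epochs(ep2, cfg$interp_s), "interpolate")
  ep2 <- run_stage(bandpass_notch(ep2, cfg$band, cfg$notch, roles = "eeg"),
                   "filter_2")
  ep2 <- run_stage(rereference_mastoids(ep2, cfg$mastoids[1], cfg$mastoids[2]),
                   "rereference")
  ep2 <- run_stage(downsample(ep2, cfg$target_rate), "downsample")
  ep2
}

#' Per-phase hotspot TEP waveforms and sham correction
#'
#' Averages the hotspot-cluster channels over trials of each phase,
#' restricted to the early-TEP window; masked (interpolated) samples are
#' excluded.
#'
#' @param ep `epochs` from [run_tep_pipeline()].
#' @param phases Per-trial phase labels (`"systole"`/`"diastole"`/...).
#' @param cfg A `tep_config`.
#' @param min_trials Minimum trials per phase.
#' @return List: `times`, one mean waveform per phase, `n` per phase.
#' @export
tep_contrast <- function(ep, phases, cfg = tep_config(), min_trials = 10) {
  stopifnot(length(phases) == dim(ep$data)[1])
  hs <- intersect(cfg$hotspot, ep$channels)
  if (length(hs) == 0) stop("no hotspot channels present")
  sel_t <- ep$times >= cfg$tep_window_s[1] & ep$times <= cfg$tep_window_s[2] &
    !ep$mask
  jj <- match(hs, ep$channels)
  out <- list(times = ep$times[sel_t], n = c())
  for (ph in c("systole", "diastole")) {
    tr <- which(phases == ph)
    if (length(tr) < min_trials)
      stop("phase cell '", ph, "' has fewer than ", min_trials, " trials")
    out[[ph]] <- apply(ep$data[tr, jj, sel_t, drop = FALSE], 3, mean)
    out$n[ph] <- length(tr)
  }
  out$diff <- out$systole - out$diastole
  out
}

#' @rdname tep_contrast
#' @param real,sham Outputs of [tep_contrast()] for the two conditions.
#' @return Sham-corrected contrast (per-phase differences real - sham).
#' @export
sham_correct_tep <- function(real, sham) {
  stopifnot(length(real$times) == length(sham$times))
  out <- list(times = real$times)
  for (ph in c("systole", "diastole")) out[[ph]] <- real[[ph]] - sham[[ph]]
  out$diff <- out$systole - out$diastole
  out
}
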