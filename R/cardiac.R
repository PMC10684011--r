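#' Remove stimulation artifacts from ECG by cubic interpolation
#'
#' Replaces the samples in a window around each stimulation (default -2 to
#' 10 ms) with a cubic spline fitted on flanking context samples;
#' overlapping windows are merged, windows at the record edge use
#' nearest-value extension. All samples outside the windows are returned
#' bit-identical.
#'
#' @param ecg Numeric vector.
#' @param event_times Stimulation times in seconds.
#' @param rate Sampling rate, Hz.
#' @param window `c(start, end)` in ms relative to each event.
#' @param flank_ms Context used on each side of a window for the spline.
#' @return Cleaned numeric vector, same length.
#' @export
interpolate_stim_artifact_ecg <- function(ecg, event_times, rate,
                                          window = c(-2, 10), flank_ms = 20) {
  if (length(event_times) == 0) return(ecg)
  n <- length(ecg)
  lo <- round(event_times * rate + window[1] / 1000 * rate) + 1
  hi <- round(event_times * rate + window[2] / 1000 * rate) + 1
  o <- order(lo); lo <- lo[o]; hi <- hi[o]
  # merge overlapping windows
  m_lo <- lo[1]; m_hi <- hi[1]; merged <- list()
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= m_hi + 1) m_hi <- max(m_hi, hi[i])
    else { merged[[length(merged) + 1]] <- c(m_lo, m_hi); m_lo <- lo[i]; m_hi <- hi[i] }
  }
  merged[[length(merged) + 1]] <- c(m_lo, m_hi)
  fl <- max(2, round(flank_ms / 1000 * rate))
  for (w in merged) {
    a <- max(1, w[1]); b <- min(n, w[2])
    if (a > b) next
    xs <- c(seq(max(1, a - fl), a - 1), seq(b + 1, min(n, b + fl)))
    xs <- xs[xs >= 1 & xs <= n]
    if (length(xs) < 4) {           # record edge: nearest-value extension
      nv <- if (a > 1) ecg[a - 1] else ecg[min(b + 1, n)]
      ecg[a:b] <- nv
    } else {
      ecg[a:b] <- stats::spline(xs, ecg[xs], xout = a:b, method = "natural")$y
    }
  }
  ecg
}

#' Detect R-peaks in an ECG trace
#'
#' Derivative-plus-moving-window-integration detector with automatic
#' polarity handling and a 250 ms refractory period. Candidate regions
#' come from the integrated squared derivative of a 5-30 Hz band-passed
#' copy; each detection is refined to the local extremum of the raw trace.
#'
#' @param ecg Numeric vector (>= 5 s of signal).
#' @param rate Sampling rate, Hz.
#' @param refractory_s Minimum peak separation.
#' @return R-peak times in seconds.
#' @export
detect_r_peaks <- function(ecg, rate, refractory_s = 0.25) {
  if (length(ecg) < 5 * rate) stop("need at least 5 s of ECG")
  bp <- signal::butter(2, c(5, min(30, rate / 2 * 0.9)) / (rate / 2), type = "pass")
  f <- signal::filtfilt(bp, ecg)
  if (abs(min(f)) > abs(max(f))) f <- -f         # auto polarity
  d2 <- c(0, diff(f))^2
  w <- max(1, round(0.15 * rate))
  integ <- stats::filter(d2, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- 0.2 * stats::quantile(integ, 0.995)
  above <- integ > thr
  if (!any(above)) stop("no R-peaks detected (flat or noisy ECG)")
  runs <- rle(above)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  cand <- numeric(0)
  half <- round(0.05 * rate)
  for (i in which(runs$values)) {
    a <- starts[i]; b <- ends[i]
    peak <- a - 1 + which.max(f[a:b])
    lo <- max(1, peak - half); hi <- min(length(ecg), peak + half)
    cand <- c(cand, lo - 1 + which.max(f[lo:hi]))
  }
  cand <- sort(unique(cand))
  # refractory: greedy keep-largest
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    if ((cand[i] - last) / rate >= refractory_s) { keep[i] <- TRUE; last <- cand[i] }
    else if (f[cand[i]] > f[cand[which(keep)[sum(keep)]]]) {
      keep[which(keep)[sum(keep)]] <- FALSE; keep[i] <- TRUE; last <- cand[i]
    }
  }
  peaks <- cand[keep]
  # quality: QRS peaks must stand far out of the background
  amp <- abs(f[peaks])
  if (length(peaks) < 3 || stats::median(amp) < 5 * stats::mad(f))
    stop("R-peak detection failed quality check (no clear QRS complexes)")
  (peaks - 1) / rate
}

#' T-wave end detection by trapezoid-area maximization
#'
#' For each beat, the T-peak is located as the signal extremum in a search
#' window after the R-peak; a reference point is placed at a fixed offset
#' beyond the search bound; the T-wave end is the sample between T-peak
#' and reference maximizing the trapezoid area
#' `A(i) = 0.5 * (y_m - y_i) * (2*x_r - x_i - x_m)`. Beats whose T-wave
#' prominence falls below `min_prominence_uv` are returned as `NA`
#' (unusable). Ties resolve to the earliest sample.
#'
#' @param ecg Numeric vector.
#' @param r_peaks R-peak times, seconds.
#' @param rate Sampling rate, Hz.
#' @param search `c(start, end)` T-peak search window, ms post-R.
#' @param ref_offset_ms Reference point offset beyond the search bound.
#' @param min_prominence_uv Minimum T-peak height over the window median.
#' @return T-end times in seconds (`NA` where unusable).
#' @export
detect_t_end <- function(ecg, r_peaks, rate, search = c(80, 450),
                         ref_offset_ms = 120, min_prominence_uv = 50) {
  n <- length(ecg)
  t_ends <- rep(NA_real_, length(r_peaks))
  for (k in seq_along(r_peaks)) {
    r_idx <- round(r_peaks[k] * rate) + 1
    next_r <- if (k < length(r_peaks)) round(r_peaks[k + 1] * rate) + 1 else n
    lo <- r_idx + round(search[1] / 1000 * rate)
    hi <- min(r_idx + round(search[2] / 1000 * rate), next_r - round(0.05 * rate))
    if (hi <= lo || hi > n) next
    seg <- ecg[lo:hi]
    base <- stats::median(seg)
    x_m <- lo - 1 + which.max(seg)
    y_m <- ecg[x_m]
    if (y_m - base < min_prominence_uv) next     # flat T: unusable
    x_r <- min(hi + round(ref_offset_ms / 1000 * rate), next_r - 1, n)
    if (x_r <= x_m + 2) next
    xi <- (x_m + 1):(x_r - 1)
    area <- 0.5 * (y_m - ecg[xi]) * (2 * x_r - xi - x_m)
    best <- xi[which.max(area)]                  # which.max: earliest on ties
    t_ends[k] <- (best - 1) / rate
  }
  t_ends
}

#' Build the per-beat cardiac phase map
#'
#' Systole is the window from the R-peak to the T-wave end; diastole is a
#' window of the same length `L` ending at the next R-peak. Beats are
#' unusable when the T-end is missing, when `rr <= 2L` (windows would
#' overlap) or when there is no next beat.
#'
#' @param r_peaks R-peak times, seconds.
#' @param t_ends Aligned T-end times ([detect_t_end()]).
#' @return data.frame of class `cardiac_map`: `r_time`, `t_end`, `rr`,
#'   `sys_len`, `dia_start`, `usable`.
#' @export
build_cardiac_map <- function(r_peaks, t_ends) {
  stopifnot(length(r_peaks) == length(t_ends))
  n <- length(r_peaks)
  rr <- c(diff(r_peaks), NA)
  l <- t_ends - r_peaks
  usable <- !is.na(t_ends) & !is.na(rr) & l > 0 & rr > 2 * l
  map <- data.frame(r_time = r_peaks, t_end = t_ends, rr = rr, sys_len = l,
                    dia_start = r_peaks + rr - l, usable = usable)
  class(map) <- c("cardiac_map", "data.frame")
  map
}

#' Classify events into cardiac phases
#'
#' Each event is `"systole"` if it falls in `[R, t_end]` of a usable beat,
#' `"diastole"` if in `[next_R - L, next_R]`, else `"neither"`. Events
#' before the first or after the last beat are `"neither"` with
#' `out_of_range = TRUE`. The distance from the preceding R-peak (ms,
#' 0-based at R) is recorded for every event with a preceding beat.
#'
#' @param event_times Event times in seconds (or an `event_list`, whose
#'   `onset_s` is used).
#' @param map A `cardiac_map`.
#' @return data.frame: `onset_s`, `phase`, `distance_ms`, `beat`,
#'   `out_of_range`.
#' @export
classify_events <- function(event_times, map) {
  if (inherits(event_times, "event_list") || is.data.frame(event_times))
    event_times <- event_times$onset_s
  k <- findInterval(event_times, map$r_time)
  n <- nrow(map)
  phase <- rep("neither", length(event_times))
  dist_ms <- rep(NA_real_, length(event_times))
  oor <- k < 1 | k >= n
  inb <- which(!oor)
  for (i in inb) {
    b <- k[i]
    off <- event_times[i] - map$r_time[b]
    dist_ms[i] <- off * 1000
    if (!map$usable[b]) next
    if (off <= map$sys_len[b]) phase[i] <- "systole"
    else if (event_times[i] >= map$dia_start[b] &&
             event_times[i] <= map$r_time[b] + map$rr[b]) phase[i] <- "diastole"
  }
  data.frame(onset_s = event_times, phase = phase, distance_ms = dist_ms,
             beat = ifelse(oor, NA_integer_, k), out_of_range = oor)
}

#' Interbeat-interval triplets around events
#'
#' For each event, the RR interval of the cycle before the event
#' (`ibi_pre`), the cycle containing it (`ibi_tms`) and the cycle after
#' (`ibi_post`), in ms. Events without a full beat on both sides are
#' dropped and counted in `attr(., "n_dropped")`.
#'
#' @param event_times Event times in seconds.
#' @param r_peaks R-peak times in seconds.
#' @param phases Optional per-event phase labels carried through.
#' @return data.frame: `event`, `phase`, `ibi_pre`, `ibi_tms`, `ibi_post`.
#' @export
ibi_triplets <- function(event_times, r_peaks, phases = NULL) {
  k <- findInterval(event_times, r_peaks)
  ok <- k >= 2 & k + 2 <= length(r_peaks)
  res <- data.frame(
    event = which(ok),
    phase = if (is.null(phases)) NA_character_ else phases[ok],
    ibi_pre = (r_peaks[k[ok]] - r_peaks[k[ok] - 1]) * 1000,
    ibi_tms = (r_peaks[k[ok] + 1] - r_peaks[k[ok]]) * 1000,
    ibi_post = (r_peaks[k[ok] + 2] - r_peaks[k[ok] + 1]) * 1000)
  attr(res, "n_dropped") <- sum(!ok)
  res
}

#' Sham-correct interbeat-interval triplets
#'
#' Subtracts the sham-condition mean from each (interval x phase) cell of
#' the real-condition triplets.
#'
#' @param real,sham Triplet data.frames from [ibi_triplets()] with phase
#'   labels.
#' @return Corrected copy of `real`.
#' @export
ibi_sham_correct <- function(real, sham) {
  for (ph in unique(real$phase)) {
    for (col in c("ibi_pre", "ibi_tms", "ibi_post")) {
      s <- sham[[col]][sham$phase == ph]
      if (length(s) == 0) stop("empty sham cell: ", ph, " x ", col)
      real[[col]][real$phase == ph] <-
        real[[col]][real$phase == ph] - mean(s)
    }
  }
  real
}
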