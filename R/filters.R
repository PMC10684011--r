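#' Zero-phase band-pass plus notch filtering
#'
#' Fourth-order Butterworth band-pass followed by a fourth-order
#' Butterworth band-stop (notch), both applied forward and backward
#' (zero net group delay). Defaults follow the package's EEG conventions:
#' 0.5-45 Hz pass band with a 45-55 Hz stop band. Only channels of the
#' given roles are touched.
#'
#' @param x A `recording` or `epochs` object.
#' @param band `c(low, high)` pass-band edges in Hz, within Nyquist.
#' @param notch_stop `c(low, high)` stop-band edges in Hz, or `NULL` to
#'   skip the notch.
#' @param order Butterworth order per filter.
#' @param roles Channel roles to filter (default all).
#' @return Object of the same class with filtered data.
#' @export
bandpass_notch <- function(x, band = c(0.5, 45), notch_stop = c(45, 55),
                           order = 4, roles = NULL) {
  nyq <- x$rate / 2
  if (max(band) >= nyq) stop("band edge at or above Nyquist (", nyq, " Hz)")
  # band-pass realised as high-pass then low-pass cascade: numerically
  # stable in transfer-function form even for sub-Hz edges at 5 kHz
  hp <- signal::butter(order, band[1] / nyq, type = "high")
  lp <- signal::butter(order, band[2] / nyq, type = "low")
  ns <- if (!is.null(notch_stop)) signal::butter(order, notch_stop / nyq, type = "stop")
  f <- function(v) {
    v <- signal::filtfilt(lp, signal::filtfilt(hp, v))
    if (!is.null(ns)) v <- signal::filtfilt(ns, v)
    v
  }
  out <- apply_traces(x, f, roles = roles)
  if (inherits(out, "epochs"))
    out$provenance <- c(out$provenance,
                        list(list(stage = "bandpass_notch", band = band,
                                  notch = notch_stop, order = order)))
  out
}

#' Re-reference EEG channels to the mastoid average
#'
#' Subtracts the average of the left and right mastoid signals from every
#' EEG-role channel (including the mastoids themselves). ECG/EMG/misc
#' channels are untouched.
#'
#' @param x A `recording` or `epochs` object.
#' @param left_label,right_label Mastoid channel labels.
#' @return Object of the same class.
#' @export
rereference_mastoids <- function(x, left_label = "M1", right_label = "M2") {
  chs <- if (inherits(x, "recording")) x$channels else x$channels
  if (!all(c(left_label, right_label) %in% chs))
    stop("missing mastoid channel(s): ",
         paste(setdiff(c(left_label, right_label), chs), collapse = ", "))
  il <- match(left_label, chs); ir <- match(right_label, chs)
  eeg <- which(x$roles == "eeg")
  if (inherits(x, "recording")) {
    ref <- (x$data[il, ] + x$data[ir, ]) / 2
    x$data[eeg, ] <- sweep(x$data[eeg, , drop = FALSE], 2, ref)
  } else {
    ref <- (x$data[, il, ] + x$data[, ir, ]) / 2   # trials x time
    for (j in eeg) x$data[, j, ] <- x$data[, j, ] - ref
    x$provenance <- c(x$provenance,
                      list(list(stage = "rereference",
                                mastoids = c(left_label, right_label))))
  }
  x
}

#' Anti-aliased downsampling
#'
#' Applies a zero-phase Butterworth low-pass at 0.45 x the new Nyquist
#' (order 6, forward-backward: >= 40 dB attenuation above the new
#' Nyquist), then decimates. Integer decimation picks every q-th sample;
#' non-integer ratios go through polyphase resampling, preserving tone
#' frequencies to well under 0.1 Hz.
#'
#' @param x A `recording` or `epochs` object.
#' @param target_rate New sampling rate in Hz (<= current rate).
#' @return Object of the same class at `target_rate`; epoch exclusion
#'   masks are carried over to the nearest surviving sample.
#' @export
downsample <- function(x, target_rate = 500) {
  if (target_rate > x$rate) stop("target_rate above current rate")
  if (target_rate == x$rate) return(x)
  aa <- signal::butter(6, 0.45 * target_rate / (x$rate / 2), type = "low")
  q <- x$rate / target_rate
  int_q <- abs(q - round(q)) < 1e-9
  f <- if (int_q) {
    function(v) signal::filtfilt(aa, v)[seq(1, length(v), by = round(q))]
  } else {
    rat <- .rational_ratio(target_rate, x$rate)
    function(v) signal::resample(signal::filtfilt(aa, v), rat[1], rat[2])
  }
  old_times <- if (inherits(x, "epochs")) x$times
  old_mask <- if (inherits(x, "epochs")) x$mask
  out <- apply_traces(x, f, new_rate = target_rate)
  if (inherits(out, "epochs")) {
    if (any(old_mask)) {
      idx <- vapply(out$times, function(t) which.min(abs(old_times - t)), 1L)
      out$mask <- old_mask[idx]
    }
    out$provenance <- c(out$provenance,
                        list(list(stage = "downsample", rate = target_rate)))
  }
  out
}

.rational_ratio <- function(p, q, max_den = 10000) {
  g <- function(a, b) if (b < 1e-9) a else g(b, a %% b)
  d <- g(p, q)
  c(round(p / d), round(q / d))
}
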