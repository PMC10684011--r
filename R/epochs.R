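#' Epoch array: trials x channels x time
#'
#' Created by [epoch()]. Carries the time axis relative to the lock event,
#' the sampling rate, channel labels/roles, per-trial metadata and a
#' logical exclusion mask over time samples (e.g. interpolated segments
#' that must not enter statistics).
#'
#' @name epochs
NULL

new_epochs <- function(data, times, rate, lock_label, channels, roles,
                       trial_meta, mask = NULL, n_dropped = 0L,
                       provenance = list()) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times),
            dim(data)[2] == length(channels),
            nrow(trial_meta) == dim(data)[1])
  if (is.null(mask)) mask <- rep(FALSE, length(times))
  structure(list(data = data, times = times, rate = rate,
                 lock_label = lock_label, channels = channels,
                 roles = roles, trial_meta = trial_meta, mask = mask,
                 n_dropped = as.integer(n_dropped), provenance = provenance),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  cat(sprintf("<epochs> %d trials x %d channels x %d samples @ %g Hz, locked to '%s' [%g, %g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate,
              x$lock_label, min(x$times), max(x$times)))
  if (x$n_dropped > 0) cat("  dropped events:", x$n_dropped, "\n")
  if (any(x$mask)) cat("  masked samples:", sum(x$mask), "\n")
  invisible(x)
}

#' Segment a recording around events
#'
#' Cuts one epoch per event of the requested label whose `[tmin, tmax]`
#' window lies fully inside the recording; out-of-range events are dropped
#' and counted (`$n_dropped`). Optional per-trial, per-channel baseline
#' subtraction using the mean over `baseline_window`.
#'
#' @param rec A `recording`.
#' @param events An `event_list`.
#' @param label Event label to lock to.
#' @param tmin,tmax Epoch window in seconds relative to the event.
#' @param baseline_window Optional `c(start, end)` in seconds for baseline
#'   mean subtraction.
#' @param channels Optional channel subset.
#' @return An `epochs` object; trial metadata carries the event rows.
#' @export
epoch <- function(rec, events, label, tmin, tmax, baseline_window = NULL,
                  channels = NULL) {
  stopifnot(tmin < tmax)
  ev <- events[events$label == label, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events with label '", label, "'")
  if (is.null(channels)) channels <- rec$channels
  n_samp <- ncol(rec$data)
  i0 <- round(ev$onset_s * rec$rate) + 1          # sample index of event
  s_lo <- i0 + round(tmin * rec$rate)
  n_t <- round((tmax - tmin) * rec$rate) + 1
  s_hi <- s_lo + n_t - 1
  keep <- s_lo >= 1 & s_hi <= n_samp
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("zero usable events for label '", label, "'")
  ev <- ev[keep, , drop = FALSE]
  s_lo <- s_lo[keep]
  times <- tmin + (seq_len(n_t) - 1) / rec$rate
  dat <- array(0, c(nrow(ev), length(channels), n_t))
  chd <- rec$data[channels, , drop = FALSE]
  for (i in seq_len(nrow(ev)))
    dat[i, , ] <- chd[, s_lo[i]:(s_lo[i] + n_t - 1)]
  ep <- new_epochs(dat, times, rec$rate, label, channels,
                   rec$roles[channels], as.data.frame(ev), n_dropped = n_dropped)
  if (!is.null(baseline_window)) ep <- baseline_correct(ep, baseline_window)
  ep
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the given time window.
#'
#' @param ep An `epochs` object.
#' @param window `c(start, end)` seconds relative to the lock event.
#' @export
baseline_correct <- function(ep, window) {
  sel <- ep$times >= window[1] & ep$times <= window[2]
  if (!any(sel)) stop("baseline window outside epoch")
  bl <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(bl)   # recycles over 3rd dim
  ep$provenance <- c(ep$provenance, list(list(stage = "baseline", window = window)))
  ep
}

# apply a per-channel-trace function over a recording or epochs object;
# f maps a numeric vector to a numeric vector of equal (or factor-reduced)
# length. roles restricts which channels are touched (NULL = all).
apply_traces <- function(x, f, roles = NULL, new_rate = NULL) {
  if (inherits(x, "recording")) {
    touch <- if (is.null(roles)) rep(TRUE, nrow(x$data)) else x$roles %in% roles
    probe <- f(x$data[1, ])
    if (length(probe) == ncol(x$data)) {
      out <- x$data
    } else {
      out <- matrix(0, nrow(x$data), length(probe), dimnames = list(rownames(x$data), NULL))
      if (any(!touch)) stop("rate-changing operation must touch all channels")
    }
    for (i in seq_len(nrow(x$data)))
      out[i, ] <- if (touch[i]) f(x$data[i, ]) else x$data[i, ]
    x$data <- out
    if (!is.null(new_rate)) x$rate <- new_rate
    x
  } else if (inherits(x, "epochs")) {
    d <- dim(x$data)
    touch <- if (is.null(roles)) rep(TRUE, d[2]) else x$roles %in% roles
    probe <- f(x$data[1, 1, ])
    new_len <- length(probe)
    out <- array(0, c(d[1], d[2], new_len))
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      out[i, j, ] <- if (touch[j]) f(x$data[i, j, ]) else x$data[i, j, ]
    x$data <- out
    if (new_len != d[3]) {
      stopifnot(!is.null(new_rate))
      x$times <- x$times[1] + (seq_len(new_len) - 1) / new_rate
      x$mask <- rep(FALSE, new_len)
    }
    if (!is.null(new_rate)) x$rate <- new_rate
    x
  } else stop("expected a recording or epochs object")
}
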