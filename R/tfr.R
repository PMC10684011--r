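#' Time-frequency analysis configuration
#'
#' Morlet scheme for sensorimotor oscillations: 5-40 Hz on a 1 Hz grid
#' with cycle counts increasing linearly from 4 to 10, epochs -1000 to
#' 4000 ms around pinch onset, relative-change ERD against a -900 to
#' -100 ms baseline, tested 8-30 Hz over 0-1000 ms at the sensorimotor
#' cluster.
#'
#' @param freqs Frequency grid, Hz.
#' @param epoch_s Epoch window, seconds.
#' @param baseline_s ERD baseline window.
#' @param test_band,test_window_s Statistical test band (Hz) and window (s).
#' @param electrodes Sensorimotor electrode cluster.
#' @return A `tfr_config` list.
#' @export
tfr_config <- function(freqs = 5:40, epoch_s = c(-1, 4),
                       baseline_s = c(-0.9, -0.1), test_band = c(8, 30),
                       test_window_s = c(0, 1),
                       electrodes = c("C4", "CP4", "C6", "CP6")) {
  structure(as.list(environment()), class = "tfr_config")
}

#' Morlet cycle count
#'
#' Cycles increase linearly from 4 at 5 Hz to 10 at 40 Hz:
#' `n(f) = 4 + 6 * (f - 5) / 35`.
#'
#' @param f Frequency in Hz, within `[5, 40]`.
#' @return Number of cycles.
#' @export
morlet_cycles <- function(f) {
  if (any(f < 5 | f > 40)) stop("frequency outside the 5-40 Hz scheme")
  4 + 6 * (f - 5) / 35
}

#' Morlet wavelet resolution
#'
#' For a wavelet of `n` cycles at frequency `f`: temporal SD
#' `sigma_t = n / (2 pi f)`, spectral SD `sigma_f = f / n`, spectral FWHM
#' `2 sqrt(2 ln 2) sigma_f`. Temporal width is reported under two
#' conventions: the Gaussian FWHM of the amplitude envelope and the
#' 2-sigma width of the power envelope (`2 sigma_t / sqrt(2)`), which
#' differ; the spectral FWHM is the figure the package treats as "the"
#' spectral resolution.
#'
#' @param f Frequency in Hz, within `[5, 40]`.
#' @return List: `n_cycles`, `sigma_t_s`, `sigma_f_hz`, `fwhm_f_hz`,
#'   `fwhm_t_s`, `power_2sigma_t_s`.
#' @export
wavelet_resolution <- function(f) {
  n <- morlet_cycles(f)
  sigma_t <- n / (2 * pi * f)
  sigma_f <- f / n
  k <- 2 * sqrt(2 * log(2))
  list(n_cycles = n, sigma_t_s = sigma_t, sigma_f_hz = sigma_f,
       fwhm_f_hz = k * sigma_f, fwhm_t_s = k * sigma_t,
       power_2sigma_t_s = 2 * sigma_t / sqrt(2))
}

# complex Morlet kernel, unit energy, support +- 3.5 sigma_t
.morlet_kernel <- function(f, rate) {
  sigma_t <- morlet_cycles(f) / (2 * pi * f)
  half <- floor(3.5 * sigma_t * rate)
  t <- (-half:half) / rate
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

# same-length complex convolution via FFT
.conv_same <- function(x, k) {
  nx <- length(x); nk <- length(k)
  n <- nx + nk - 1
  y <- stats::fft(stats::fft(c(x, rep(0, n - nx))) *
                  stats::fft(c(k, rep(0, n - nk))), inverse = TRUE) / n
  y[((nk - 1) %/% 2 + 1):((nk - 1) %/% 2 + nx)]
}

#' Morlet wavelet time-frequency power
#'
#' Power = squared magnitude of the convolution with a unit-energy
#' complex Morlet wavelet, per trial, channel and frequency. Samples
#' within half the wavelet support of either epoch edge are flagged in
#' the `edge` attribute (freqs x times logical).
#'
#' @param ep `epochs`.
#' @param cfg A `tfr_config`.
#' @param channels Channel subset (default: configured electrodes present).
#' @return List: `power` (trials x channels x freqs x times), `freqs`,
#'   `times`, `channels`, `edge`.
#' @export
compute_tfr <- function(ep, cfg = tfr_config(), channels = NULL) {
  if (is.null(channels)) channels <- intersect(cfg$electrodes, ep$channels)
  if (length(channels) == 0) stop("no requested channels present")
  jj <- match(channels, ep$channels)
  n_tr <- dim(ep$data)[1]; n_t <- dim(ep$data)[3]
  lowest <- min(cfg$freqs)
  support <- 2 * floor(3.5 * (morlet_cycles(lowest) / (2 * pi * lowest)) *
                         ep$rate) + 1
  if (n_t < support)
    stop("epoch too short for the wavelet support at ", lowest,
         " Hz; lowest valid frequency is higher")
  kernels <- lapply(cfg$freqs, .morlet_kernel, rate = ep$rate)
  power <- array(0, c(n_tr, length(jj), length(cfg$freqs), n_t))
  edge <- matrix(FALSE, length(cfg$freqs), n_t)
  for (fi in seq_along(cfg$freqs)) {
    half <- (length(kernels[[fi]]) - 1) / 2
    edge[fi, c(seq_len(min(half, n_t)),
               seq(max(1, n_t - half + 1), n_t))] <- TRUE
    for (i in seq_len(n_tr)) for (j in seq_along(jj))
      power[i, j, fi, ] <- Mod(.conv_same(ep$data[i, jj[j], ],
                                          kernels[[fi]]))^2
  }
  list(power = power, freqs = cfg$freqs, times = ep$times,
       channels = channels, edge = edge)
}

#' Event-related desynchronization maps and phase contrast
#'
#' ERD is the relative power change against the per-trial baseline mean,
#' `(power - baseline) / baseline`, per channel and frequency; trial
#' means are then formed per cardiac phase. The output arrays are the
#' input for spatio-spectral cluster permutation testing.
#'
#' @param tfr Output of [compute_tfr()].
#' @param phases Per-trial phase labels.
#' @param cfg A `tfr_config`.
#' @return List: `erd` (trials x channels x freqs x times),
#'   per-phase maps (`systole`, `diastole`: channels x freqs x times),
#'   `contrast` (systole - diastole), `freqs`, `times`, `channels`.
#' @export
erd_contrast <- function(tfr, phases, cfg = tfr_config()) {
  bsel <- tfr$times >= cfg$baseline_s[1] & tfr$times <= cfg$baseline_s[2]
  if (!any(bsel)) stop("ERD baseline window outside epoch")
  d <- dim(tfr$power)
  erd <- tfr$power
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (fi in seq_len(d[3])) {
    b <- mean(tfr$power[i, j, fi, bsel])
    erd[i, j, fi, ] <- (tfr$power[i, j, fi, ] - b) / b
  }
  out <- list(erd = erd, freqs = tfr$freqs, times = tfr$times,
              channels = tfr$channels)
  for (ph in c("systole", "diastole")) {
    tr <- which(phases == ph)
    if (length(tr) > 0)
      out[[ph]] <- apply(erd[tr, , , , drop = FALSE], c(2, 3, 4), mean)
  }
  if (!is.null(out$systole) && !is.null(out$diastole))
    out$contrast <- out$systole - out$diastole
  out
}
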