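# Minimal EDF (European Data Format) I/O: 16-bit integer storage with
# per-channel linear physical scaling. Covers plain EDF continuous
# recordings (no annotations); enough for interoperable exchange of the
# multichannel sessions this package analyses.

.edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Data are stored as 16-bit integers with per-channel physical min/max
#' taken from the data range, i.e. quantised to ~1/65535 of each channel's
#' range. One data record holds the full recording.
#'
#' @param rec A `recording`.
#' @param path Output file path.
#' @export
write_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  con <- file(path, "wb")
  on.exit(close(con))
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmax_[flat] <- pmin_[flat] + 1
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X", 80), .edf_pad("X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (ns + 1), 8), .edf_pad("", 44),
    .edf_pad(1, 8), .edf_pad(format(n_samp / rec$rate, digits = 8), 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    .edf_pad(rec$channels, 16),
    .edf_pad(rep("", ns), 80),
    .edf_pad(rep(rec$units, ns), 8),
    .edf_pad(formatC(pmin_, format = "g", digits = 6), 8),
    .edf_pad(formatC(pmax_, format = "g", digits = 6), 8),
    .edf_pad(rep(-32768L, ns), 8),
    .edf_pad(rep(32767L, ns), 8),
    .edf_pad(rep("", ns), 80),
    .edf_pad(rep(n_samp, ns), 8),
    .edf_pad(rep("", ns), 32))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- round((rec$data[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @param roles Optional role overrides, as in [recording()].
#' @return A `recording`; channel roles inferred from labels unless
#'   overridden.
#' @export
read_edf <- function(path, roles = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns <= 0) stop("corrupt EDF header in ", path)
  rdv <- function(width) {
    v <- vapply(seq_len(ns), function(i) rd(width), character(1))
    trimws(v)
  }
  labels <- rdv(16); rdv(80); units <- rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80); spr <- as.integer(rdv(8)); rdv(32)
  expect_bytes <- 2 * n_rec * sum(spr)
  raw_ <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                  signed = TRUE, endian = "little")
  if (length(raw_) * 2 < expect_bytes)
    stop("truncated EDF file: ", path)
  data <- matrix(0, ns, n_rec * spr[1])
  if (length(unique(spr)) != 1)
    stop("inconsistent channel lengths (samples per record differ) in ", path)
  idx <- 0
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- raw_[(idx + 1):(idx + spr[i])]
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin_[i] + (seg - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i])
      idx <- idx + spr[i]
    }
  }
  rate <- spr[1] / rec_dur
  rownames(data) <- labels
  recording(data, rate = rate, channels = labels, roles = roles,
            units = if (nzchar(units[1])) units[1] else "uV")
}
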