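#' Multichannel continuous recording
#'
#' Container for a continuous electrophysiological recording: a channels x
#' samples matrix with a sampling rate, per-channel role tags and declared
#' units. Internal representation is microvolts throughout.
#'
#' @param data Numeric matrix, channels x samples; rownames are channel
#'   labels (set from `channels` if missing).
#' @param rate Sampling rate in Hz (> 0).
#' @param channels Channel labels; defaults to rownames of `data`.
#' @param roles Named character vector mapping labels to one of
#'   `"eeg"`, `"ecg"`, `"emg"`, `"misc"`. Missing entries are inferred
#'   from the label ([infer_roles()]).
#' @param units Unit string, declared once per recording.
#' @param montage Optional data.frame of 2-D positions for EEG channels.
#' @return Object of class `recording`.
#' @export
recording <- function(data, rate, channels = rownames(data), roles = NULL,
                      units = "uV", montage = NULL) {
  data <- as.matrix(data)
  if (is.null(channels)) stop("channel labels required")
  if (length(channels) != nrow(data))
    stop("channel label count does not match data rows")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a single positive number")
  rownames(data) <- channels
  full_roles <- infer_roles(channels)
  if (!is.null(roles)) full_roles[names(roles)] <- unname(roles)
  bad <- !full_roles %in% c("eeg", "ecg", "emg", "misc")
  if (any(bad)) stop("invalid role(s): ", paste(unique(full_roles[bad]), collapse = ", "))
  structure(list(data = data, rate = rate, channels = channels,
                 roles = full_roles, units = units, montage = montage),
            class = "recording")
}

#' Infer channel roles from label conventions
#'
#' `ECG*` -> ecg, `EMG*` -> emg, parsable 10-10 names -> eeg, else misc.
#'
#' @param labels Channel labels.
#' @return Named character vector of roles.
#' @export
infer_roles <- function(labels) {
  roles <- vapply(labels, function(lab) {
    if (grepl("^ECG", lab, ignore.case = TRUE)) return("ecg")
    if (grepl("^EMG", lab, ignore.case = TRUE)) return("emg")
    if (grepl("^[A-Za-z]+?(z|[0-9]+)$", lab)) return("eeg")
    "misc"
  }, character(1))
  names(roles) <- labels
  roles
}

#' @export
print.recording <- function(x, ...) {
  dur <- ncol(x$data) / x$rate
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s, %s)\n",
              nrow(x$data), ncol(x$data), x$rate, dur, x$units))
  tab <- table(x$roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `recording`.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$rate

#' Labelled event stream
#'
#' Events are held as a data.frame with columns `onset_s` (seconds from
#' recording start) and `label`, plus arbitrary per-event metadata columns.
#' Rows are kept sorted by onset.
#'
#' @param onset_s Event times in seconds.
#' @param label Event labels (e.g. `"tms"`, `"sham"`, `"rpeak"`,
#'   `"pinch_on"`, `"mock"`, `"rest_probe"`).
#' @param ... Further per-event metadata vectors (recycled like data.frame).
#' @return data.frame of class `event_list`, sorted by onset.
#' @export
event_list <- function(onset_s, label, ...) {
  df <- data.frame(onset_s = as.numeric(onset_s),
                   label = as.character(label), ...,
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_list", "data.frame")
  df
}

#' Write / read a recording as a delimited-text bundle
#'
#' The bundle is a directory containing one TSV per channel role
#' (samples x channels, header = labels) and a `meta.json` sidecar with
#' the rate, units and role map. This is the package's plain-text exchange
#' format; EDF is supported separately for interoperability.
#'
#' @param rec A `recording`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (role in unique(rec$roles)) {
    chs <- rec$channels[rec$roles == role]
    m <- t(rec$data[chs, , drop = FALSE])
    colnames(m) <- chs
    utils::write.table(format(m, digits = 10, trim = TRUE, scientific = TRUE),
                       file.path(path, paste0(role, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(rate = rec$rate, units = rec$units,
               channels = rec$channels, roles = as.list(rec$roles))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param format `"bundle"` (delimited-text directory) or `"edf"`.
#' @export
read_recording <- function(path, format = c("bundle", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path))
  if (!dir.exists(path)) stop("unreadable recording bundle: ", path)
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("unreadable recording bundle (no meta.json): ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  roles <- unlist(meta$roles)
  mats <- list()
  for (role in unique(roles)) {
    f <- file.path(path, paste0(role, ".tsv"))
    if (!file.exists(f)) stop("missing channel-group file: ", f)
    m <- as.matrix(utils::read.table(f, header = TRUE, sep = "\t",
                                     check.names = FALSE))
    mats[[role]] <- t(m)
  }
  ns <- unique(vapply(mats, ncol, 1L))
  if (length(ns) != 1)
    stop("inconsistent channel lengths across groups in ", path)
  data <- do.call(rbind, unname(mats))
  data <- data[meta$channels, , drop = FALSE]
  recording(data, rate = meta$rate, channels = meta$channels,
            roles = roles, units = meta$units)
}

#' Write / read events as TSV
#'
#' Columns: `onset_s`, `label`, `meta` (JSON object of any further
#' per-event fields).
#'
#' @param ev An `event_list`.
#' @param path TSV file path.
#' @export
write_events <- function(ev, path) {
  extra <- setdiff(names(ev), c("onset_s", "label"))
  meta <- if (length(extra)) {
    vapply(seq_len(nrow(ev)), function(i)
      as.character(jsonlite::toJSON(as.list(ev[i, extra, drop = FALSE]),
                                    auto_unbox = TRUE, digits = NA,
                                    null = "null", na = "null")),
      character(1))
  } else rep("{}", nrow(ev))
  out <- data.frame(onset_s = ev$onset_s, label = ev$label, meta = meta)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  metas <- lapply(df$meta, function(s) jsonlite::fromJSON(s))
  keys <- unique(unlist(lapply(metas, names)))
  args <- list(onset_s = df$onset_s, label = df$label)
  for (k in keys) {
    vals <- lapply(metas, function(m) {
      v <- m[[k]]
      if (is.null(v) || length(v) == 0) NA else v
    })
    numeric_ok <- all(vapply(vals, function(v) is.numeric(v) || is.logical(v) || all(is.na(v)), logical(1)))
    args[[k]] <- if (numeric_ok) vapply(vals, as.numeric, numeric(1))
                 else vapply(vals, as.character, character(1))
  }
  do.call(event_list, args)
}
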