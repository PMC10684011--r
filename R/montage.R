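#' Standard EEG channel set
#'
#' The 62-channel 10-10 layout used by the synthetic-session generator and
#' the default analysis configurations, plus the two mastoid reference
#' channels (`M1`, `M2`) appended at the end.
#'
#' @return Character vector of channel labels (EEG first, then mastoids).
#' @export
default_eeg_channels <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "I1", "I2",
    "M1", "M2")
}

# row letters -> anterior/posterior grid coordinate
.row_y <- c(Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, T = 0, C = 0,
            TP = -1, CP = -1, M = -1, P = -2, PO = -3, O = -4, I = -5)

#' Approximate 2-D montage positions from 10-10 labels
#'
#' Positions are derived from the label grammar alone: the letter block
#' selects the anterior-posterior row, the digit the signed lateral
#' coordinate (odd = left, even = right, `z` = midline). The resulting
#' unit-spaced grid is sufficient for neighbourhood (adjacency) graphs;
#' it is not a digitised head model.
#'
#' @param labels Character vector of 10-10 channel labels.
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
standard_montage <- function(labels) {
  parse_one <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    if (length(m) == 0) stop("unrecognised channel label: ", lab)
    row <- m[2]; num <- m[3]
    if (!row %in% names(.row_y)) stop("unrecognised channel row: ", lab)
    y <- .row_y[[row]]
    if (num == "z") {
      x <- 0
    } else {
      n <- as.integer(num)
      x <- ceiling(n / 2) * if (n %% 2 == 1) -1 else 1
      # T7/T8 and TP/FT rows sit on the C +-4 line
      if (row %in% c("T", "TP", "FT")) x <- sign(x) * 4
      if (row == "M") x <- sign(x) * 5
    }
    c(x = x, y = y)
  }
  pos <- t(vapply(labels, parse_one, c(x = 0, y = 0)))
  data.frame(label = labels, x = pos[, "x"], y = pos[, "y"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Channel adjacency graph from montage distances
#'
#' Two channels are neighbours when their montage distance is at most
#' `threshold` grid units (default 1.5: the 8 surrounding grid positions).
#' The result is a symmetric logical matrix without self-edges, the spatial
#' part of the neighbourhood structure used by [cluster_perm_test()].
#'
#' @param labels Channel labels (10-10 names) or a montage data.frame as
#'   returned by [standard_montage()].
#' @param threshold Distance cut-off in grid units.
#' @return Symmetric logical matrix with dimnames = labels.
#' @export
channel_adjacency <- function(labels, threshold = 1.5) {
  mont <- if (is.data.frame(labels)) labels else standard_montage(labels)
  d <- as.matrix(stats::dist(mont[, c("x", "y")]))
  adj <- d > 0 & d <= threshold
  dimnames(adj) <- list(mont$label, mont$label)
  adj
}
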