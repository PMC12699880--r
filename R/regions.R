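#' Assign 10-20 channels to scalp regions
#'
#' Deterministic prefix rule partitioning a montage into the three regions
#' used by the regional connectivity summaries -- frontal (F), central (C)
#' and parieto-occipital (PO) -- plus `other` for labels that match no
#' 10-20 prefix. Two-letter prefixes take precedence over single letters, so
#' `FC*`/`CP*` are central and `Fp*`/`AF*` frontal.
#'
#' Rule: `Fp`, `AF`, `F` -> frontal; `FC`, `CP`, `C`, `T` -> central;
#' `TP`, `PO`, `P`, `O` -> parieto_occipital. On the standard 19-channel
#' 10-20 montage this yields 7 frontal, 7 central, 5 parieto-occipital.
#'
#' @param channel_labels character vector of channel names.
#' @return Named character vector (class `region_map`) mapping each label to
#'   `"frontal"`, `"central"`, `"parieto_occipital"` or `"other"`.
#' @examples
#' assign_regions(c("Fp1", "Cz", "O2", "X99"))
#' @export
assign_regions <- function(channel_labels) {
  channel_labels <- as.character(channel_labels)
  up <- toupper(channel_labels)
  region <- rep("other", length(up))
  two <- substr(up, 1L, 2L)
  one <- substr(up, 1L, 1L)
  region[two %in% c("FP", "AF")] <- "frontal"
  region[two %in% c("FC", "CP")] <- "central"
  region[two %in% c("TP", "PO")] <- "parieto_occipital"
  rest <- region == "other" & !(two %in% c("FP", "AF", "FC", "CP", "TP", "PO"))
  region[rest & one == "F"] <- "frontal"
  region[rest & one %in% c("C", "T")] <- "central"
  region[rest & one %in% c("P", "O")] <- "parieto_occipital"
  structure(stats::setNames(region, channel_labels), class = "region_map")
}

#' The standard 19-channel 10-20 montage
#' @return Character vector of the 19 standard 10-20 labels.
#' @export
standard_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

# Approximate 2-D scalp coordinates (x = right, y = anterior, unit circle)
# for the standard 10-20 montage; used to synthesize canonical microstate
# topographies.
standard_1020_xy <- function() {
  m <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7 = c(-0.81, 0.59), F3 = c(-0.55, 0.67), Fz = c(0, 0.72),
    F4 = c(0.55, 0.67), F8 = c(0.81, 0.59),
    T3 = c(-1.00, 0.00), C3 = c(-0.67, 0.00), Cz = c(0, 0),
    C4 = c(0.67, 0.00), T4 = c(1.00, 0.00),
    T5 = c(-0.81, -0.59), P3 = c(-0.55, -0.67), Pz = c(0, -0.72),
    P4 = c(0.55, -0.67), T6 = c(0.81, -0.59),
    O1 = c(-0.31, -0.95), O2 = c(0.31, -0.95))
  colnames(m) <- c("x", "y")
  m
}
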