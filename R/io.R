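#' Read a recording from disk
#'
#' Two on-disk forms are supported. The canonical fixture format is a
#' delimited channels x samples matrix (tab-separated, no header) plus a JSON
#' sidecar declaring `fs`, `channel_labels`, and optionally `state_label` and
#' `subject_id`. Files ending in `.edf` are read as 16-bit EDF instead
#' (read-only convenience; see [write_edf()] for the matching writer).
#'
#' @param path data file (`.tsv` matrix or `.edf`).
#' @param sidecar_path JSON sidecar; defaults to `path` with a `.json`
#'   extension. Ignored for EDF.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, sidecar_path = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  side <- read_sidecar(path, sidecar_path, c("fs", "channel_labels"))
  mat <- as.matrix(read.delim(path, header = FALSE))
  dimnames(mat) <- NULL
  eeg_recording(mat, fs = side$fs, channel_labels = side$channel_labels,
                state_label = side$state_label %||% "unknown",
                subject_id = side$subject_id %||% "s01")
}

#' Write a recording in the canonical fixture format
#'
#' @param recording an [eeg_recording()].
#' @param path output path for the tab-separated matrix; the JSON sidecar is
#'   written next to it.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  utils::write.table(recording$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  side <- list(fs = recording$fs, channel_labels = recording$channel_labels,
               state_label = recording$state_label,
               subject_id = recording$subject_id)
  jsonlite::write_json(side, sidecar_path_for(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write evoked epochs
#'
#' Epochs are stored as a `(trials * channels) x samples` tab-separated
#' matrix (trial-major row order) plus a JSON sidecar declaring `fs`,
#' `onset_index`, `n_trials` and `channel_labels`.
#'
#' @param path data file.
#' @param sidecar_path JSON sidecar; defaults to `path` with `.json`.
#' @param epochs an [eeg_epochs()].
#' @return `read_epochs` returns an [eeg_epochs()]; `write_epochs` invisibly
#'   returns `path`.
#' @export
read_epochs <- function(path, sidecar_path = NULL) {
  side <- read_sidecar(path, sidecar_path,
                       c("fs", "onset_index", "n_trials", "channel_labels"))
  mat <- as.matrix(read.delim(path, header = FALSE))
  dimnames(mat) <- NULL
  n_trials <- as.integer(side$n_trials)
  n_ch <- length(side$channel_labels)
  if (nrow(mat) != n_trials * n_ch)
    stop(sprintf("shape mismatch: %d rows, expected %d trials x %d channels",
                 nrow(mat), n_trials, n_ch))
  arr <- array(0, c(n_trials, n_ch, ncol(mat)))
  for (tr in seq_len(n_trials))
    arr[tr, , ] <- mat[(tr - 1L) * n_ch + seq_len(n_ch), , drop = FALSE]
  eeg_epochs(arr, fs = side$fs, onset_index = side$onset_index,
             channel_labels = side$channel_labels)
}

#' @rdname read_epochs
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  mat <- matrix(0, d[1] * d[2], d[3])
  for (tr in seq_len(d[1]))
    mat[(tr - 1L) * d[2] + seq_len(d[2]), ] <- epochs$data[tr, , ]
  utils::write.table(mat, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  side <- list(fs = epochs$fs, onset_index = epochs$onset_index,
               n_trials = d[1], channel_labels = epochs$channel_labels)
  jsonlite::write_json(side, sidecar_path_for(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path_for <- function(path) paste0(sub("\\.[^./]+$", "", path), ".json")

read_sidecar <- function(path, sidecar_path, required) {
  if (is.null(sidecar_path)) sidecar_path <- sidecar_path_for(path)
  if (!file.exists(sidecar_path))
    stop("missing sidecar file: ", sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  missing <- setdiff(required, names(side))
  if (length(missing))
    stop("sidecar is missing required fields: ", paste(missing, collapse = ", "))
  side
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimal 16-bit EDF reader and writer
#'
#' Standard European Data Format: 256-byte fixed header, 256 bytes of
#' per-signal header fields, then little-endian 16-bit data records. The
#' writer emits one channel per signal with per-channel physical scaling, so
#' a round trip preserves the data to 16-bit quantization of each channel's
#' amplitude range. Reading is a convenience for externally produced files;
#' the delimited matrix + sidecar format is the canonical one.
#'
#' @param path file path.
#' @param recording an [eeg_recording()]; `fs` must be a whole number (EDF
#'   records here span one second).
#' @param state_label,subject_id metadata applied to the recording on read
#'   (EDF carries no state field).
#' @return `read_edf` returns an [eeg_recording()]; `write_edf` invisibly
#'   returns `path`.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  x <- recording$data
  ns <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1L) stop("recording shorter than one 1-s EDF record")
  x <- x[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(x, 1L, min); pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(s, 1L, w)
    writeChar(formatC(s, width = -w, flag = " "), con, nchars = w, eos = NULL)
  }
  pad("0", 8)
  pad(recording$subject_id, 80)
  pad(recording$state_label, 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(as.character(256L + 256L * ns), 8)
  pad("", 44)
  pad(as.character(n_rec), 8)
  pad("1", 8)
  pad(as.character(ns), 4)
  for (lab in recording$channel_labels) pad(lab, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (v in pmin_) pad(formatC(v, digits = 6, format = "g"), 8)
  for (v in pmax_) pad(formatC(v, digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) pad(as.character(dmin), 8)
  for (i in seq_len(ns)) pad(as.character(dmax), 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(as.character(fs), 8)
  for (i in seq_len(ns)) pad("", 32)
  # physical value p maps to digital d = (p - pmin)/(pmax - pmin)*(dmax - dmin) + dmin
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    for (i in seq_len(ns)) {
      d <- (x[i, idx] - pmin_[i]) / (pmax_[i] - pmin_[i]) * (dmax - dmin) + dmin
      writeBin(as.integer(round(d)), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path, state_label = NULL, subject_id = NULL) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  pid <- rd(80); rinfo <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      p <- (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) + pmin_[i]
      out[i, (r - 1L) * spr[i] + seq_len(spr[i])] <- p
    }
  }
  eeg_recording(out, fs = spr[1] / rec_dur, channel_labels = labels,
                state_label = state_label %||%
                  (if (nzchar(rinfo)) rinfo else "unknown"),
                subject_id = subject_id %||% (if (nzchar(pid)) pid else "s01"))
}

#' Write / read a feature table
#'
#' The long-format output contract shared by all feature pipelines: one row
#' per `(subject, state, channel, feature)` with a numeric `value`. Written
#' as CSV with a fixed column order and a single header line; channel may
#' name a single electrode, a region, or `whole_brain`.
#'
#' @param rows data.frame with columns `subject`, `state`, `channel`,
#'   `feature`, `value`.
#' @param path output CSV path.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns the data.frame.
#' @export
write_feature_table <- function(rows, path) {
  cols <- c("subject", "state", "channel", "feature", "value")
  missing <- setdiff(cols, names(rows))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  rows <- rows[, cols]
  if (!is.numeric(rows$value)) stop("`value` column must be numeric")
  write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
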