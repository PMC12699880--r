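#' Continuous multichannel EEG recording
#'
#' Container for a resting-state EEG segment: a channels x samples matrix in
#' microvolts plus its sampling rate, ordered channel labels, a free-form
#' state label (e.g. `"awake"`, `"moderate_sedation"`, `"UWS"`) and a subject
#' identifier. All spontaneous-activity analyses in the package operate on
#' this class.
#'
#' @param data numeric matrix, channels x samples (microvolts). All values
#'   must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per row of `data`;
#'   10-20 names where available. Defaults to `"ch1" ... "chN"`.
#' @param state_label free string tagging the behavioural/clinical state.
#' @param subject_id subject identifier string.
#'
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_labels`, `state_label`, `subject_id`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(500), 2), fs = 50)
#' duration(rec)
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          state_label = "unknown", subject_id = "s01") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (nrow(data) < 1L) stop("recording must contain at least one channel")
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop(sprintf("shape mismatch: %d channel labels for %d data rows",
                 length(channel_labels), nrow(data)))
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         state_label = as.character(state_label),
         subject_id = as.character(subject_id)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), state=%s, subject=%s\n",
              nrow(x$data), ncol(x$data), x$fs, duration(x), x$state_label,
              x$subject_id))
  invisible(x)
}

#' Recording duration in seconds
#' @param x an `eeg_recording`.
#' @return Length in seconds (`samples / fs`).
#' @export
duration <- function(x) ncol(x$data) / x$fs

#' Apply an average (common) reference
#'
#' Subtracts the instantaneous mean across channels from every sample. Global
#' field power and microstate topographies are reference-dependent; the
#' average reference is the microstate-literature convention and is applied
#' by the microstate and topography pipelines unless disabled there.
#'
#' @param x an `eeg_recording` or a channels x samples / channels-long matrix.
#' @return Object of the same type, re-referenced.
#' @export
average_reference <- function(x) {
  if (inherits(x, "eeg_recording")) {
    x$data <- sweep(x$data, 2L, colMeans(x$data))
    return(x)
  }
  m <- as.matrix(x)
  sweep(m, 2L, colMeans(m))
}

#' TMS-evoked epochs
#'
#' Trials x channels x samples array of peri-stimulus EEG with the stimulus
#' onset expressed as a 0-based sample index into the third dimension.
#'
#' @param data numeric array `trials x channels x samples` (microvolts).
#' @param fs sampling rate (Hz).
#' @param onset_index 0-based sample index of stimulus delivery;
#'   `0 <= onset_index < samples`.
#' @param channel_labels one label per channel.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, onset_index, channel_labels = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be trials x channels x samples")
  storage.mode(data) <- "double"
  if (dim(data)[1] < 1L) stop("need at least one trial")
  if (!all(is.finite(data))) stop("epochs contain non-finite samples")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  onset_index <- as.integer(onset_index)
  if (onset_index < 0L || onset_index >= dim(data)[3])
    stop(sprintf("onset_index %d outside sample range [0, %d)",
                 onset_index, dim(data)[3]))
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(data)[2]))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != dim(data)[2])
    stop("label count does not equal channel count")
  structure(list(data = data, fs = fs, onset_index = onset_index,
                 channel_labels = channel_labels),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d ch x %d samples @ %g Hz, onset at sample %d\n",
              d[1], d[2], d[3], x$fs, x$onset_index))
  invisible(x)
}

#' Quality report for a recording
#'
#' Report-only screen: flags non-finite samples, flat (zero-variance)
#' channels, and a sampling rate below twice the highest configured band
#' edge (Nyquist violation for the requested bands).
#'
#' @param recording an `eeg_recording`.
#' @param config an [analysis_config()]; its band edges set the Nyquist check.
#' @return A data.frame with columns `check`, `channel`, `message`; zero rows
#'   when the recording is clean.
#' @export
validate_recording <- function(recording, config = analysis_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  rows <- list()
  nf <- which(apply(recording$data, 1L, function(r) any(!is.finite(r))))
  for (i in nf)
    rows[[length(rows) + 1L]] <- data.frame(
      check = "non_finite", channel = recording$channel_labels[i],
      message = "channel contains non-finite samples")
  v <- apply(recording$data, 1L, var)
  for (i in which(v == 0))
    rows[[length(rows) + 1L]] <- data.frame(
      check = "flat_channel", channel = recording$channel_labels[i],
      message = "zero-variance (flat) channel")
  f_hi <- max(vapply(config$bands, `[`, numeric(1), 2L))
  if (recording$fs < 2 * f_hi)
    rows[[length(rows) + 1L]] <- data.frame(
      check = "nyquist", channel = NA_character_,
      message = sprintf("fs = %g Hz below 2 x highest band edge (needs fs >= %g)",
                        recording$fs, 2 * f_hi))
  if (length(rows) == 0L)
    return(data.frame(check = character(), channel = character(),
                      message = character()))
  do.call(rbind, rows)
}
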