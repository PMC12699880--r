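#' Trial-averaged evoked response
#'
#' Averages epochs across trials and subtracts, per channel, the mean over
#' the baseline window (seconds relative to stimulus onset, half-open
#' `[t0, t1)`).
#'
#' @param epochs an [eeg_epochs()].
#' @param baseline `c(t0, t1)` seconds relative to onset; must lie inside
#'   the recorded pre/post span. `NULL` skips baseline correction.
#' @return channels x samples matrix of the baseline-corrected evoked
#'   response, with attributes `fs` and `onset_index`.
#' @export
average_evoked <- function(epochs, baseline = c(-0.1, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  ev <- apply(epochs$data, c(2, 3), mean)
  if (!is.null(baseline)) {
    idx0 <- epochs$onset_index + round(baseline[1] * epochs$fs)
    idx1 <- epochs$onset_index + round(baseline[2] * epochs$fs)
    if (idx0 < 0 || idx1 > d[3] || idx1 <= idx0)
      stop("baseline window outside the recorded span")
    bl <- rowMeans(ev[, (idx0 + 1L):idx1, drop = FALSE])
    ev <- ev - bl
  }
  rownames(ev) <- epochs$channel_labels
  attr(ev, "fs") <- epochs$fs
  attr(ev, "onset_index") <- epochs$onset_index
  ev
}

#' PCA of the evoked response in a post-stimulus window
#'
#' Eigendecomposition of the channels x channels correlation matrix of the
#' evoked response computed across the time points of the window (default
#' 0-300 ms post-stimulus, half-open). Channels are standardized over the
#' window, so the eigenvalues sum to the channel count and the
#' eigenvalue-greater-than-1 criterion of [effective_dimensionality()] is
#' meaningful. PC scores are the standardized data projected on the
#' eigenvectors.
#'
#' @param evoked an [average_evoked()] result (channels x samples with `fs`
#'   and `onset_index` attributes), or any matrix plus explicit `fs` /
#'   `onset_index`.
#' @param window `c(t0, t1)` seconds post-stimulus.
#' @param fs,onset_index overrides for plain-matrix input.
#' @return A list of class `evoked_decomposition`: `eigenvalues`
#'   (decreasing), `vectors`, `pc_scores` (time x components),
#'   `explained_variance`, `window`, `fs`, `times` (seconds, relative to
#'   onset).
#' @export
pca_window <- function(evoked, window = c(0, 0.3), fs = attr(evoked, "fs"),
                       onset_index = attr(evoked, "onset_index")) {
  if (is.null(fs) || is.null(onset_index))
    stop("`fs` and `onset_index` must be available")
  n_ch <- nrow(evoked)
  if (n_ch < 2) stop("need at least 2 channels")
  i0 <- onset_index + round(window[1] * fs)
  i1 <- onset_index + round(window[2] * fs)
  if (i0 < 0 || i1 > ncol(evoked) || i1 <= i0)
    stop("window outside the evoked span")
  seg <- evoked[, (i0 + 1L):i1, drop = FALSE] # half-open [t0, t1)
  n_t <- ncol(seg)
  if (n_t < n_ch)
    warning("fewer time points than channels; eigenvalues are rank-deficient")
  mu <- rowMeans(seg)
  sdv <- sqrt(rowSums((seg - mu)^2) / n_t)
  if (any(sdv == 0)) stop("zero-variance channel inside the window")
  z <- (seg - mu) / sdv
  r <- tcrossprod(z) / n_t
  ed <- eigen(r, symmetric = TRUE)
  ev <- pmax(ed$values, 0)
  structure(list(
    eigenvalues = ev, vectors = ed$vectors,
    pc_scores = crossprod(z, ed$vectors),
    explained_variance = ev / sum(ev),
    window = window, fs = fs,
    times = (seq(i0, i1 - 1L) - onset_index) / fs),
    class = "evoked_decomposition")
}

#' Effective dimensionality of an eigenvalue spectrum
#'
#' The number of eigenvalues strictly greater than 1 divided by the
#' fraction of total variance those eigenvalues explain. Defined on
#' correlation-matrix spectra (trace = number of channels): a rank-1
#' response gives 1; richer responses give larger values, never below the
#' count of above-1 eigenvalues. When no eigenvalue exceeds 1 the value is
#' 0 with attribute `degenerate = TRUE`.
#'
#' @param eigenvalues non-negative eigenvalues, or an
#'   `evoked_decomposition`.
#' @return A list of class `effective_dimensionality`: `ed`, `n_above`,
#'   `cum_var_fraction`.
#' @export
effective_dimensionality <- function(eigenvalues) {
  if (inherits(eigenvalues, "evoked_decomposition"))
    eigenvalues <- eigenvalues$eigenvalues
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative")
  if (all(eigenvalues == 0)) stop("all-zero eigenvalue spectrum")
  above <- eigenvalues > 1
  n_above <- sum(above)
  if (n_above == 0L) {
    return(structure(list(ed = 0, n_above = 0L, cum_var_fraction = 0,
                          degenerate = TRUE),
                     class = "effective_dimensionality"))
  }
  cvf <- sum(eigenvalues[above]) / sum(eigenvalues)
  structure(list(ed = n_above / cvf, n_above = n_above,
                 cum_var_fraction = cvf),
            class = "effective_dimensionality")
}

#' @export
print.effective_dimensionality <- function(x, ...) {
  cat(sprintf("ED = %.3f (%d eigenvalues > 1 explaining %.1f%% of variance)\n",
              x$ed, x$n_above, 100 * x$cum_var_fraction))
  invisible(x)
}

#' Export the PC trajectory
#'
#' Time-stamped coordinates of the evoked response in PC space over the
#' analysis window, at the recording's sampling grid.
#'
#' @param decomposition a [pca_window()] result.
#' @param n_components number of components to export.
#' @return A data.frame with columns `t` (s) and `PC1 ... PCn`.
#' @export
trajectory_export <- function(decomposition, n_components = 2) {
  stopifnot(inherits(decomposition, "evoked_decomposition"))
  if (n_components > ncol(decomposition$pc_scores))
    stop("more components requested than available")
  out <- data.frame(t = decomposition$times)
  for (i in seq_len(n_components))
    out[[paste0("PC", i)]] <- decomposition$pc_scores[, i]
  out
}

#' Evoked feature rows for an epochs object
#'
#' @param epochs an [eeg_epochs()].
#' @param window analysis window, seconds post-stimulus.
#' @param baseline baseline window, seconds relative to onset.
#' @return A data.frame with columns `channel` (`"global"`), `feature`
#'   (`ed`, `pc1_var`) and `value`.
#' @export
evoked_features <- function(epochs, window = c(0, 0.3),
                            baseline = c(-0.1, 0)) {
  ev <- average_evoked(epochs, baseline)
  dec <- pca_window(ev, window)
  ed <- effective_dimensionality(dec)
  data.frame(channel = "global", feature = c("ed", "pc1_var"),
             value = c(ed$ed, dec$explained_variance[1L]))
}
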