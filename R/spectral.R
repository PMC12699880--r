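#' Windowed power spectral density
#'
#' Welch-style estimate: the recording is cut into windows of
#' `window_s` seconds (default 10 s, non-overlapping; any partial trailing
#' window is discarded), each window is mean-detrended, tapered and
#' transformed, and the one-sided periodograms are averaged per channel.
#' With the default Hann taper the estimate uses the standard power
#' normalization, so the PSD integrates to the signal variance (Parseval);
#' a rectangular taper is available for exactness checks on pure tones.
#'
#' @param recording an [eeg_recording()] of duration >= `window_s`.
#' @param window_s window length in seconds; the frequency resolution is
#'   `1/window_s`.
#' @param overlap fractional overlap between consecutive windows in `[0, 1)`.
#' @param taper `"hann"` or `"rect"`.
#' @return An object of class `spectral_estimate`: list with `freqs` (Hz),
#'   `psd` (channels x freqs, uV^2/Hz), `window_s`, `n_windows`, `fs`,
#'   `channel_labels`.
#' @examples
#' rec <- eeg_recording(matrix(sin(2 * pi * 10 * (1:2500) / 250), 1), 250)
#' est <- compute_psd(rec, window_s = 10)
#' est$freqs[which.max(est$psd[1, ])]
#' @export
compute_psd <- function(recording, window_s = 10, overlap = 0,
                        taper = c("hann", "rect")) {
  stopifnot(inherits(recording, "eeg_recording"))
  taper <- match.arg(taper)
  fs <- recording$fs
  nper <- round(window_s * fs)
  n <- ncol(recording$data)
  if (n < nper) stop("recording shorter than one window")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- if (taper == "hann") signal::hanning(nper) else rep(1, nper)
  u <- sum(w^2)
  n_freq <- nper %/% 2L + 1L
  freqs <- (seq_len(n_freq) - 1L) / window_s
  nc <- nrow(recording$data)
  psd <- matrix(0, nc, n_freq)
  for (s0 in starts) {
    seg <- recording$data[, s0:(s0 + nper - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, w, `*`)
    sp <- Mod(stats::mvfft(t(seg)))^2
    psd <- psd + t(sp[seq_len(n_freq), , drop = FALSE])
  }
  psd <- psd / (length(starts) * fs * u)
  dbl <- rep(2, n_freq); dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[n_freq] <- 1
  psd <- sweep(psd, 2L, dbl, `*`)
  structure(list(freqs = freqs, psd = psd, window_s = window_s,
                 n_windows = length(starts), fs = fs,
                 channel_labels = recording$channel_labels),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d ch x %d freqs (0-%g Hz, df=%g), %d windows of %g s\n",
              nrow(x$psd), length(x$freqs), max(x$freqs), 1 / x$window_s,
              x$n_windows, x$window_s))
  invisible(x)
}

band_bins <- function(freqs, band) {
  idx <- which(freqs >= band[1] & freqs <= band[2])
  if (length(idx) == 0L) stop("band is empty on this frequency grid")
  idx
}

trapz_rows <- function(psd, freqs, idx) {
  if (length(idx) == 1L) return(psd[, idx] * 0)
  f <- freqs[idx]
  p <- psd[, idx, drop = FALSE]
  dx <- diff(f)
  as.numeric((p[, -length(idx), drop = FALSE] +
                p[, -1L, drop = FALSE]) %*% dx) / 2
}

#' Relative band power
#'
#' Per-channel fraction of total power carried by a band: the trapezoidal
#' integral of the PSD over the band divided by its integral over
#' `total_range` (default 1-45 Hz, the union span of the default delta,
#' alpha and low-gamma bands). Scale-invariant by construction.
#'
#' @param estimate a [compute_psd()] result.
#' @param band `c(f_lo, f_hi)` Hz, contained in `total_range`.
#' @param total_range denominator range `c(lo, hi)` Hz.
#' @return Named numeric vector, one fraction in `[0, 1]` per channel.
#' @export
relative_band_power <- function(estimate, band, total_range = c(1, 45)) {
  stopifnot(inherits(estimate, "spectral_estimate"))
  if (band[1] < total_range[1] || band[2] > total_range[2])
    stop("band must be contained in total_range")
  num <- trapz_rows(estimate$psd, estimate$freqs,
                    band_bins(estimate$freqs, band))
  den <- trapz_rows(estimate$psd, estimate$freqs,
                    band_bins(estimate$freqs, total_range))
  stats::setNames(num / den, estimate$channel_labels)
}

#' Band center frequency
#'
#' Power-weighted mean frequency (spectral centroid) over the in-band bins:
#' `sum(f * P(f)) / sum(P(f))`. The centroid always lies inside the band and
#' coincides with the peak frequency for symmetric unimodal in-band spectra;
#' an argmax-peak variant is available via `method = "peak"`.
#'
#' @param estimate a [compute_psd()] result.
#' @param band `c(f_lo, f_hi)` Hz.
#' @param method `"centroid"` (default) or `"peak"`.
#' @return Named numeric vector, one frequency (Hz) per channel.
#' @export
center_frequency <- function(estimate, band, method = c("centroid", "peak")) {
  stopifnot(inherits(estimate, "spectral_estimate"))
  method <- match.arg(method)
  idx <- band_bins(estimate$freqs, band)
  p <- estimate$psd[, idx, drop = FALSE]
  f <- estimate$freqs[idx]
  tot <- rowSums(p)
  if (any(tot <= 0)) stop("zero in-band power on some channel")
  out <- if (method == "centroid") as.numeric(p %*% f) / tot
         else f[apply(p, 1L, which.max)]
  stats::setNames(out, estimate$channel_labels)
}

#' Per-band spectral features for a recording
#'
#' Convenience wrapper computing relative power and center frequency for
#' every configured band.
#'
#' @param recording an [eeg_recording()].
#' @param config an [analysis_config()].
#' @return A data.frame with columns `channel`, `feature`
#'   (`relpow_<band>` / `cf_<band>`) and `value`.
#' @export
band_features <- function(recording, config = analysis_config()) {
  est <- compute_psd(recording, config$psd_window_s, config$psd_overlap)
  rows <- list()
  for (bn in names(config$bands)) {
    rp <- relative_band_power(est, config$bands[[bn]], config$total_range)
    cf <- center_frequency(est, config$bands[[bn]])
    rows[[length(rows) + 1L]] <- data.frame(
      channel = names(rp), feature = paste0("relpow_", bn), value = unname(rp))
    rows[[length(rows) + 1L]] <- data.frame(
      channel = names(cf), feature = paste0("cf_", bn), value = unname(cf))
  }
  do.call(rbind, rows)
}

#' Regional and whole-brain topographic summary
#'
#' Arithmetic mean of a per-channel quantity within each scalp region of a
#' region map, plus the whole-brain mean. A region containing no channel is
#' reported as `NA`.
#'
#' @param values named numeric vector (names = channel labels).
#' @param region_map an [assign_regions()] result covering those channels.
#' @return A named numeric vector with elements `whole_brain`, `frontal`,
#'   `central`, `parieto_occipital` (and `other` if present in the map).
#' @export
band_topography <- function(values, region_map) {
  missing <- setdiff(names(values), names(region_map))
  if (length(missing))
    stop("channels not covered by region map: ", paste(missing, collapse = ", "))
  regs <- c("frontal", "central", "parieto_occipital")
  if (any(region_map == "other")) regs <- c(regs, "other")
  out <- c(whole_brain = mean(values))
  for (r in regs) {
    ch <- names(region_map)[region_map == r]
    ch <- intersect(ch, names(values))
    out[r] <- if (length(ch)) mean(values[ch]) else NA_real_
  }
  out
}
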