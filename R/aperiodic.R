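#' Autocorrelation function
#'
#' Biased (1/n-normalized) sample autocorrelation for lags `0..max_lag`,
#' with `ACF(0) = 1` exactly.
#'
#' @param signal numeric vector with non-zero variance.
#' @param max_lag maximum lag in samples (`< length(signal)`).
#' @return Numeric vector of length `max_lag + 1`.
#' @export
autocorrelation <- function(signal, max_lag) {
  if (max_lag >= length(signal)) stop("max_lag must be < signal length")
  if (var(signal) == 0) stop("zero-variance signal")
  as.numeric(acf(signal, lag.max = max_lag, plot = FALSE,
                 demean = TRUE)$acf)
}

#' Autocorrelation window (ACW)
#'
#' Intrinsic-timescale estimate: the first lag at which the autocorrelation
#' function falls strictly below `threshold` times its lag-0 peak (default
#' 50%), converted to seconds. The crossing is the first passage below the
#' threshold with no sub-sample interpolation. Invariant to amplitude
#' scaling of the signal.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param threshold decay threshold as a fraction of the peak.
#' @param max_lag search horizon in samples (default 5 s or the signal
#'   length, whichever is smaller).
#' @return ACW in seconds, or `NA` (with attribute `no_crossing = TRUE`)
#'   when the ACF never falls below the threshold within `max_lag`.
#' @examples
#' acw50(rnorm(10000), fs = 100) # white noise: first lag, 0.01 s
#' @export
acw50 <- function(signal, fs, threshold = 0.5,
                  max_lag = min(length(signal) - 1L, round(5 * fs))) {
  a <- autocorrelation(signal, max_lag)
  k <- which(a < threshold)
  if (length(k) == 0L) {
    out <- NA_real_
    attr(out, "no_crossing") <- TRUE
    return(out)
  }
  (k[1L] - 1L) / fs
}

#' ACW of a recording, per channel
#'
#' Splits each channel into non-overlapping segments (default 10 s),
#' computes the ACW per segment and averages; segments with no threshold
#' crossing are dropped.
#'
#' @param recording an [eeg_recording()].
#' @param segment_s segment length in seconds; `Inf` uses the whole channel.
#' @param threshold decay threshold.
#' @return Named numeric vector of per-channel ACW values (seconds).
#' @export
acw_features <- function(recording, segment_s = 10, threshold = 0.5) {
  fs <- recording$fs
  n <- ncol(recording$data)
  seg_len <- if (is.finite(segment_s)) round(segment_s * fs) else n
  starts <- seq(1L, n - seg_len + 1L, by = seg_len)
  out <- vapply(seq_len(nrow(recording$data)), function(ch) {
    vals <- vapply(starts, function(s0) {
      acw50(recording$data[ch, s0:(s0 + seg_len - 1L)], fs, threshold,
            max_lag = seg_len - 1L)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(out, recording$channel_labels)
}

#' Detrended fluctuation analysis
#'
#' Scaling exponent of the root-mean-square fluctuation of the integrated,
#' piecewise-detrended signal versus window size. The signal is cumulated
#' after mean removal; each scale's non-overlapping windows are detrended by
#' a least-squares polynomial of the given order; the exponent is the
#' least-squares slope of `log F(s)` against `log s`. An exponent of 0.5
#' marks uncorrelated noise and values above 0.5 long-range temporal
#' correlation; for `1/f^chi` noise the exponent is `(chi + 1) / 2`.
#'
#' @param signal numeric vector (non-constant).
#' @param scales integer window sizes in samples; default 20 log-spaced
#'   scales from 16 to `length(signal)/4`.
#' @param order detrending polynomial order (only order 1, linear, is
#'   implemented).
#' @return The scaling exponent, with attributes `scales` and `fluctuation`.
#' @examples
#' dfa(rnorm(5000)) # ~0.5
#' @export
dfa <- function(signal, scales = NULL, order = 1) {
  n <- length(signal)
  if (var(signal) == 0) stop("constant signal")
  if (order != 1) stop("only order-1 (linear) detrending is implemented")
  if (is.null(scales))
    scales <- unique(round(exp(seq(log(16), log(n / 4), length.out = 20))))
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 2) stop("need at least 2 scales")
  if (max(scales) > n / 2) stop("largest scale exceeds half the signal length")
  prof <- cumsum(signal - mean(signal))
  fluct <- vapply(scales, function(s) {
    m <- floor(n / s)
    y <- matrix(prof[seq_len(m * s)], nrow = s)
    # closed-form linear detrend per column: residual SS =
    # Syy - Sty^2 / Stt with t centered
    t0 <- seq_len(s) - (s + 1) / 2
    stt <- sum(t0^2)
    ybar <- colMeans(y)
    syy <- colSums(y^2) - s * ybar^2
    sty <- as.numeric(crossprod(t0, y))
    rss <- pmax(syy - sty^2 / stt, 0)
    sqrt(mean(rss) / s)
  }, numeric(1))
  fit <- lm(log(fluct) ~ log(scales))
  out <- unname(coef(fit)[2L])
  attr(out, "scales") <- scales
  attr(out, "fluctuation") <- fluct
  out
}

#' Aperiodic (1/f) fit of a power spectrum
#'
#' Robust line fit in log-log coordinates over `fit_range` (default
#' 1-30 Hz) with iterative oscillatory-peak pruning: after an ordinary
#' least-squares fit, bins whose positive residuals exceed 2.5 robust
#' standard deviations (1.4826 x MAD) are flagged as peaks and the line is
#' refit on the remaining bins, repeating until the flagged set is stable
#' (at most 10 iterations). The reported exponent is the negative slope, so
#' steeper low-frequency dominance gives a larger exponent.
#'
#' @param estimate a [compute_psd()] result, or a list with `freqs` and
#'   `psd` (channels x freqs).
#' @param fit_range `c(lo, hi)` Hz with at least 10 bins inside.
#' @param peak_sd residual threshold in robust standard deviations.
#' @param max_iter maximum pruning iterations.
#' @return A data.frame with one row per channel: `offset` (log10 power at
#'   1 Hz), `exponent`, `r_squared`, `n_excluded`; attribute `peak_mask`
#'   holds the channels x bins logical matrix of excluded bins, attribute
#'   `freqs` the in-range frequency grid.
#' @export
fit_aperiodic <- function(estimate, fit_range = c(1, 30), peak_sd = 2.5,
                          max_iter = 10) {
  idx <- which(estimate$freqs >= fit_range[1] & estimate$freqs <= fit_range[2])
  if (length(idx) < 10) stop("need at least 10 frequency bins in fit_range")
  f <- estimate$freqs[idx]
  psd <- estimate$psd[, idx, drop = FALSE]
  if (any(psd <= 0)) stop("non-positive PSD values inside fit_range")
  lx <- log10(f)
  nc <- nrow(psd)
  out <- data.frame(offset = numeric(nc), exponent = numeric(nc),
                    r_squared = numeric(nc), n_excluded = integer(nc))
  mask <- matrix(FALSE, nc, length(idx))
  for (ch in seq_len(nc)) {
    ly <- log10(psd[ch, ])
    keep <- rep(TRUE, length(ly))
    for (it in seq_len(max_iter)) {
      ft <- lm(ly ~ lx, subset = keep)
      resid_all <- ly - (coef(ft)[1L] + coef(ft)[2L] * lx)
      rsd <- mad(resid_all[keep])
      if (rsd == 0) break
      new_keep <- resid_all <= peak_sd * rsd
      if (sum(new_keep) < 5)
        stop("fewer than 5 bins survive peak exclusion")
      if (identical(new_keep, keep)) break
      keep <- new_keep
    }
    ft <- lm(ly ~ lx, subset = keep)
    pred <- coef(ft)[1L] + coef(ft)[2L] * lx
    ss_res <- sum((ly[keep] - pred[keep])^2)
    ss_tot <- sum((ly[keep] - mean(ly[keep]))^2)
    out$offset[ch] <- unname(coef(ft)[1L])
    out$exponent[ch] <- -unname(coef(ft)[2L])
    out$r_squared[ch] <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    out$n_excluded[ch] <- sum(!keep)
    mask[ch, ] <- !keep
  }
  if (!is.null(estimate$channel_labels))
    out$channel <- estimate$channel_labels
  attr(out, "peak_mask") <- mask
  attr(out, "freqs") <- f
  out
}

#' Aperiodic features of a recording
#'
#' Convenience wrapper: per-channel ACW, DFA exponent and 1/f fit.
#'
#' @param recording an [eeg_recording()].
#' @param config an [analysis_config()].
#' @param include character subset of `c("acw", "dfa", "1f")`.
#' @return A data.frame with columns `channel`, `feature` (`acw`, `dfa`,
#'   `exponent_1f`, `offset_1f`) and `value`.
#' @export
aperiodic_features <- function(recording, config = analysis_config(),
                               include = c("acw", "dfa", "1f")) {
  rows <- list()
  if ("acw" %in% include) {
    acw <- acw_features(recording, segment_s = config$psd_window_s,
                        threshold = config$acw_threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      channel = names(acw), feature = "acw", value = unname(acw))
  }
  if ("dfa" %in% include) {
    d <- apply(recording$data, 1L, function(x) as.numeric(dfa(x)))
    rows[[length(rows) + 1L]] <- data.frame(
      channel = recording$channel_labels, feature = "dfa", value = d)
  }
  if ("1f" %in% include) {
    est <- compute_psd(recording, config$psd_window_s, config$psd_overlap)
    ft <- fit_aperiodic(est, config$aperiodic_fit_range)
    rows[[length(rows) + 1L]] <- data.frame(
      channel = recording$channel_labels, feature = "exponent_1f",
      value = ft$exponent)
    rows[[length(rows) + 1L]] <- data.frame(
      channel = recording$channel_labels, feature = "offset_1f",
      value = ft$offset)
  }
  do.call(rbind, rows)
}
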