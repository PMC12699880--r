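#' Analysis configuration
#'
#' Bundles every tunable parameter of the feature pipelines. Defaults follow
#' the printed conventions of the validation analyses this package
#' implements: 10-s non-overlapping PSD windows; delta 1-4 Hz, alpha 8-13 Hz
#' and low-gamma 30-45 Hz bands; aperiodic fit over 1-30 Hz; autocorrelation
#' window at 50% decay; 5% display density for the strongest connections;
#' four microstate classes; a 0-300 ms evoked window; FDR level q = 0.05.
#'
#' @param bands named list of `c(f_lo, f_hi)` Hz pairs.
#' @param psd_window_s PSD window length, seconds.
#' @param psd_overlap fractional window overlap in `[0, 1)`.
#' @param total_range denominator range (Hz) for relative band power; the
#'   union span of the default bands.
#' @param aperiodic_fit_range `c(lo, hi)` Hz for the 1/f fit.
#' @param acw_threshold autocorrelation decay threshold (fraction of peak).
#' @param pcmi_m,pcmi_tau,pcmi_max_lag ordinal embedding dimension, lag and
#'   maximum cross-lag (samples) for permutation cross-mutual information.
#' @param display_density proportional threshold used when exporting the
#'   strongest connections for display.
#' @param graph_density proportional threshold density at which graph metrics
#'   are computed by default.
#' @param density_sweep vector of densities over which graph metrics are also
#'   emitted, to avoid single-threshold cherry-picking.
#' @param n_surrogates degree-preserving rewired null networks per graph.
#' @param microstate_k number of microstate classes.
#' @param evoked_window `c(t0, t1)` seconds post-stimulus for evoked PCA.
#' @param fdr_q false-discovery-rate level.
#' @param seed integer seed driving any randomized step.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(bands = list(delta = c(1, 4), alpha = c(8, 13),
                                         low_gamma = c(30, 45)),
                            psd_window_s = 10, psd_overlap = 0,
                            total_range = c(1, 45),
                            aperiodic_fit_range = c(1, 30),
                            acw_threshold = 0.5,
                            pcmi_m = 3L, pcmi_tau = 1L, pcmi_max_lag = 10L,
                            display_density = 0.05,
                            graph_density = 0.15,
                            density_sweep = seq(0.05, 0.30, by = 0.05),
                            n_surrogates = 100L,
                            microstate_k = 4L,
                            evoked_window = c(0, 0.3),
                            fdr_q = 0.05,
                            seed = 1L) {
  for (b in bands)
    if (length(b) != 2L || b[1] >= b[2])
      stop("each band must be c(f_lo, f_hi) with f_lo < f_hi")
  for (d in c(display_density, graph_density, density_sweep))
    if (d <= 0 || d > 1) stop("densities must lie in (0, 1]")
  if (psd_overlap < 0 || psd_overlap >= 1) stop("psd_overlap must be in [0, 1)")
  if (acw_threshold <= 0 || acw_threshold >= 1)
    stop("acw_threshold must be in (0, 1)")
  structure(list(
    bands = bands, psd_window_s = psd_window_s, psd_overlap = psd_overlap,
    total_range = total_range, aperiodic_fit_range = aperiodic_fit_range,
    acw_threshold = acw_threshold, pcmi_m = as.integer(pcmi_m),
    pcmi_tau = as.integer(pcmi_tau), pcmi_max_lag = as.integer(pcmi_max_lag),
    display_density = display_density, graph_density = graph_density,
    density_sweep = density_sweep, n_surrogates = as.integer(n_surrogates),
    microstate_k = as.integer(microstate_k), evoked_window = evoked_window,
    fdr_q = fdr_q, seed = as.integer(seed)), class = "analysis_config")
}

#' Read / write an analysis configuration
#'
#' Configurations round-trip through a JSON file whose keys mirror the
#' [analysis_config()] argument names.
#'
#' @param path file path.
#' @param config an `analysis_config`.
#' @return `read_config` returns an `analysis_config`; `write_config`
#'   invisibly returns `path`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$bands)) raw$bands <- lapply(raw$bands, as.numeric)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
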