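#' Permutation cross-mutual information between two signals
#'
#' Both signals are ordinal-symbolized ([ordinal_patterns()]) and the
#' mutual information between the two symbol streams is computed at every
#' signed cross-lag `-max_lag..max_lag` (equivalently, both directions of
#' each non-negative lag) and maximized over the lag, which makes the
#' measure symmetric in its arguments.
#' The plug-in estimator carries a Miller-Madow bias correction, so
#' independent streams score near 0 bits. For `y = x` the value equals the
#' pattern entropy of `x` (self-information ceiling); the measure is
#' symmetric in its arguments by construction.
#'
#' @param x,y equal-length numeric signals.
#' @param m,tau ordinal embedding dimension and lag.
#' @param max_lag maximum cross-lag in samples.
#' @return PCMI in bits, with attributes `lag` (maximizing lag) and
#'   `profile` (value per lag).
#' @export
pcmi_pair <- function(x, y, m = 3, tau = 1, max_lag = 10) {
  if (length(x) != length(y)) stop("signals must have equal length")
  sx <- ordinal_patterns(x, m, tau)
  sy <- ordinal_patterns(y, m, tau)
  k <- attr(sx, "alphabet")
  if (k^2 > length(sx) / 10)
    warning("joint ordinal alphabet undersampled: m!^2 > n/10")
  prof <- .mi_lag_profile_cpp(as.integer(sx), as.integer(sy),
                              as.integer(k), as.integer(max_lag))
  best <- which.max(prof)
  out <- prof[best]
  attr(out, "lag") <- best - 1L
  attr(out, "profile") <- prof
  out
}

# FFT analytic signal (positive-frequency doubling); returns complex vector
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Phase lag index between two signals
#'
#' Both signals are band-pass filtered (zero-phase FIR), instantaneous
#' phases are taken from the analytic signal, and the PLI is the absolute
#' time average of the sign of the phase difference,
#' `|mean(sign(sin(phi_x - phi_y)))|`. Zero-lag (volume-conduction-like)
#' coupling scores 0 because `sign(0) = 0`; a constant non-zero phase lead
#' scores 1.
#'
#' @param x,y equal-length signals.
#' @param band `c(f_lo, f_hi)` Hz within `(0, fs/2)`.
#' @param fs sampling rate (Hz).
#' @param filter_order FIR filter order.
#' @return PLI in `[0, 1]`.
#' @export
pli_pair <- function(x, y, band = c(8, 13), fs, filter_order = 64) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (band[1] <= 0 || band[2] >= fs / 2) stop("band must lie within (0, fs/2)")
  bp <- signal::fir1(filter_order, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  yf <- signal::filtfilt(bp, y)
  if (var(xf) == 0 || var(yf) == 0) stop("zero variance after filtering")
  dphi <- Arg(analytic_signal(xf)) - Arg(analytic_signal(yf))
  abs(mean(sign(sin(dphi))))
}

#' Pairwise connectivity matrix of a recording
#'
#' Computes the chosen pairwise measure for every unordered channel pair and
#' returns a symmetric matrix with zero diagonal.
#'
#' @param recording an [eeg_recording()] with >= 2 channels.
#' @param method `"pcmi"` (broadband ordinal mutual information, default)
#'   or `"pli"` (band-filtered phase lag index).
#' @param m,tau,max_lag PCMI parameters.
#' @param band PLI band (Hz).
#' @return An object of class `connectivity_result`: list with `matrix`
#'   (channels x channels), `method` and `params`.
#' @export
connectivity_matrix <- function(recording, method = c("pcmi", "pli"),
                                m = 3, tau = 1, max_lag = 10,
                                band = c(8, 13)) {
  stopifnot(inherits(recording, "eeg_recording"))
  method <- match.arg(method)
  nc <- nrow(recording$data)
  if (nc < 2) stop("need at least 2 channels")
  w <- matrix(0, nc, nc, dimnames = list(recording$channel_labels,
                                         recording$channel_labels))
  if (method == "pcmi") {
    syms <- lapply(seq_len(nc), function(ch)
      ordinal_patterns(recording$data[ch, ], m, tau))
    k <- factorial(m)
    for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
      prof <- .mi_lag_profile_cpp(as.integer(syms[[i]]),
                                  as.integer(syms[[j]]),
                                  as.integer(k), as.integer(max_lag))
      w[i, j] <- w[j, i] <- max(prof)
    }
    params <- list(m = m, tau = tau, max_lag = max_lag)
  } else {
    for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc)
      w[i, j] <- w[j, i] <- pli_pair(recording$data[i, ],
                                     recording$data[j, ], band, recording$fs)
    params <- list(band = band)
  }
  structure(list(matrix = w, method = method, params = params),
            class = "connectivity_result")
}

#' Proportional threshold to a binary adjacency matrix
#'
#' Keeps the `ceiling(density * K)` largest of the `K = n(n-1)/2`
#' upper-triangle weights (ties broken by stable index order) and returns
#' the corresponding symmetric 0/1 adjacency matrix.
#'
#' @param matrix symmetric weight matrix (or a `connectivity_result`).
#' @param density fraction of possible edges to keep, in `(0, 1]`.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
threshold_proportional <- function(matrix, density) {
  if (inherits(matrix, "connectivity_result")) matrix <- matrix$matrix
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  n <- nrow(matrix)
  ut <- which(upper.tri(matrix))
  w <- matrix[ut]
  if (length(unique(w)) == 1L)
    warning("all weights equal: edge selection is a pure tie-break")
  keep_n <- ceiling(density * length(ut))
  ord <- order(w, decreasing = TRUE) # stable ties by index
  adj <- matrix * 0
  adj[ut[ord[seq_len(keep_n)]]] <- 1
  adj + t(adj)
}

adj_to_graph <- function(adjacency) {
  igraph::graph_from_adjacency_matrix(adjacency != 0, mode = "undirected",
                                      diag = FALSE)
}

largest_component <- function(g) {
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership ==
                                      which.max(comp$csize)))
}

#' Mean clustering coefficient
#'
#' Average over nodes of the local clustering coefficient
#' (triangles / possible triangles); nodes of degree < 2 contribute 0.
#'
#' @param adjacency binary symmetric adjacency matrix.
#' @return Mean clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(adjacency) {
  g <- adj_to_graph(adjacency)
  if (igraph::ecount(g) == 0) stop("empty graph")
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Characteristic path length
#'
#' Mean shortest-path length over all unordered node pairs of the graph; if
#' the graph is disconnected, computed on the largest connected component
#' and flagged via attribute `disconnected = TRUE`.
#'
#' @param adjacency binary symmetric adjacency matrix.
#' @return Mean geodesic distance (>= 1 for non-trivial graphs).
#' @export
characteristic_path_length <- function(adjacency) {
  g <- adj_to_graph(adjacency)
  if (igraph::ecount(g) == 0) stop("graph has no edges")
  disconnected <- !igraph::is_connected(g)
  if (disconnected) g <- largest_component(g)
  out <- igraph::mean_distance(g, directed = FALSE)
  if (disconnected) attr(out, "disconnected") <- TRUE
  out
}

#' Small-worldness against degree-preserving nulls
#'
#' `sigma = (C / C_rand) / (L / L_rand)` where `C_rand` and `L_rand` are the
#' mean clustering coefficient and characteristic path length of
#' `n_surrogates` degree-preserving rewirings of the graph (double edge
#' swaps, `10 x edges` swaps each). Random graphs score approximately 1;
#' genuinely small-world graphs (clustered, short paths) score above 1.
#'
#' @param adjacency binary symmetric adjacency matrix (>= 10 nodes
#'   recommended).
#' @param n_surrogates number of rewired null networks.
#' @param seed integer seed for the rewiring.
#' @return Sigma, with attributes `C`, `L`, `C_rand`, `L_rand`,
#'   `n_surrogates`.
#' @export
small_worldness <- function(adjacency, n_surrogates = 100, seed = 1L) {
  g <- adj_to_graph(adjacency)
  if (igraph::ecount(g) < 2) stop("too few edges to rewire")
  cc <- clustering_coefficient(adjacency)
  ll <- as.numeric(characteristic_path_length(adjacency))
  n_swap <- 10L * igraph::ecount(g)
  nulls <- local_seed(seed, {
    vapply(seq_len(n_surrogates), function(i) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swap))
      grc <- if (igraph::is_connected(gr)) gr else largest_component(gr)
      c(igraph::transitivity(gr, type = "localaverage", isolates = "zero"),
        igraph::mean_distance(grc, directed = FALSE))
    }, numeric(2))
  })
  c_rand <- mean(nulls[1L, ])
  l_rand <- mean(nulls[2L, ])
  if (c_rand == 0)
    stop("null networks have no triangles; sigma undefined")
  out <- (cc / c_rand) / (ll / l_rand)
  attr(out, "C") <- cc; attr(out, "L") <- ll
  attr(out, "C_rand") <- c_rand; attr(out, "L_rand") <- l_rand
  attr(out, "n_surrogates") <- n_surrogates
  out
}

#' Regional connectivity summary
#'
#' Averages a connectivity matrix over the whole brain (all off-diagonal
#' pairs), within the frontal (F), central (C) and parieto-occipital (PO)
#' regions, and between each region pair. A region with fewer than 2
#' channels yields `NA` for its within-region mean.
#'
#' @param matrix symmetric connectivity matrix with channel dimnames (or a
#'   `connectivity_result`).
#' @param region_map an [assign_regions()] result.
#' @return Named numeric vector with elements `W`, `F`, `C`, `PO`, `F-C`,
#'   `C-PO`, `F-PO`.
#' @export
regional_summary <- function(matrix, region_map) {
  if (inherits(matrix, "connectivity_result")) matrix <- matrix$matrix
  labs <- rownames(matrix)
  if (is.null(labs)) stop("matrix must carry channel labels as dimnames")
  reg <- unname(region_map[labs])
  block_mean <- function(ra, rb) {
    ia <- which(reg == ra); ib <- which(reg == rb)
    if (ra == rb) {
      if (length(ia) < 2) return(NA_real_)
      sub <- matrix[ia, ia, drop = FALSE]
      mean(sub[upper.tri(sub)])
    } else {
      if (length(ia) == 0 || length(ib) == 0) return(NA_real_)
      mean(matrix[ia, ib])
    }
  }
  c(W = mean(matrix[upper.tri(matrix)]),
    `F` = block_mean("frontal", "frontal"),
    C = block_mean("central", "central"),
    PO = block_mean("parieto_occipital", "parieto_occipital"),
    `F-C` = block_mean("frontal", "central"),
    `C-PO` = block_mean("central", "parieto_occipital"),
    `F-PO` = block_mean("frontal", "parieto_occipital"))
}

#' Network features of a recording
#'
#' PCMI connectivity with regional summaries plus graph metrics
#' (clustering coefficient, characteristic path length, small-worldness)
#' at the default threshold density and across the configured density sweep.
#'
#' @param recording an [eeg_recording()].
#' @param config an [analysis_config()].
#' @param densities densities at which to emit graph metrics; defaults to
#'   the union of `config$graph_density` and `config$density_sweep`.
#' @param n_surrogates surrogates per small-worldness estimate.
#' @return A data.frame with columns `channel` (region or `graph`),
#'   `feature` and `value`.
#' @export
network_features <- function(recording, config = analysis_config(),
                             densities = NULL,
                             n_surrogates = config$n_surrogates) {
  conn <- connectivity_matrix(recording, "pcmi", m = config$pcmi_m,
                              tau = config$pcmi_tau,
                              max_lag = config$pcmi_max_lag)
  reg <- regional_summary(conn, assign_regions(recording$channel_labels))
  rows <- data.frame(channel = "region", feature = paste0("pcmi_", names(reg)),
                     value = unname(reg))
  if (is.null(densities))
    densities <- sort(unique(c(config$graph_density, config$density_sweep)))
  for (d in densities) {
    adj <- threshold_proportional(conn$matrix, d)
    sig <- small_worldness(adj, n_surrogates = n_surrogates,
                           seed = config$seed)
    rows <- rbind(rows, data.frame(
      channel = "graph",
      feature = sprintf(c("C_density%g", "L_density%g", "sigma_density%g"), d),
      value = c(attr(sig, "C"), attr(sig, "L"), as.numeric(sig))))
  }
  rows
}

#' Export an adjacency or weight matrix as an edge list
#'
#' @param matrix symmetric matrix with channel dimnames.
#' @param path output path (tab-separated `node_i`, `node_j`, `weight`).
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(matrix, path) {
  if (inherits(matrix, "connectivity_result")) matrix <- matrix$matrix
  ut <- which(upper.tri(matrix), arr.ind = TRUE)
  df <- data.frame(node_i = rownames(matrix)[ut[, 1]],
                   node_j = colnames(matrix)[ut[, 2]],
                   weight = matrix[ut])
  df <- df[df$weight != 0, ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
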