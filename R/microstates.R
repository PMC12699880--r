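# Average-reference each map (row) and scale it to unit L2 norm.
normalize_maps <- function(maps) {
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  sweep(maps, 1L, ifelse(nrm > 0, nrm, 1), `/`)
}

# |spatial correlation| between unit-norm centered template rows (k x ch)
# and map columns (ch x n): returns k x n matrix of absolute correlations.
abs_spatial_corr <- function(templates, maps_t) {
  cent <- maps_t - rep(colMeans(maps_t), each = nrow(maps_t))
  nrm <- sqrt(colSums(cent^2))
  a <- abs(templates %*% cent)
  sweep(a, 2L, ifelse(nrm > 0, nrm, Inf), `/`)
}

#' Global field power
#'
#' Spatial standard deviation (population formula) of the scalp map at each
#' sample, after average referencing. GFP peaks mark moments of high
#' topographic signal-to-noise and are the standard sampling points for
#' microstate clustering.
#'
#' @param x an [eeg_recording()] (>= 2 channels) or channels x samples
#'   matrix.
#' @param reference `"average"` (default) or `"none"` if the data are
#'   already referenced.
#' @return Numeric vector, one GFP value per sample.
#' @export
gfp <- function(x, reference = c("average", "none")) {
  reference <- match.arg(reference)
  m <- if (inherits(x, "eeg_recording")) x$data else as.matrix(x)
  if (nrow(m) < 2) stop("GFP requires at least 2 channels")
  if (reference == "average") m <- sweep(m, 2L, colMeans(m))
  sqrt(colMeans(m^2))
}

#' GFP peak detection
#'
#' Strict local maxima of a GFP series, optionally enforcing a minimum
#' peak-to-peak distance (default 10 ms): peaks are accepted greedily in
#' order of decreasing height, suppressing any later peak closer than the
#' minimum distance to an accepted one.
#'
#' @param gfp_series numeric vector (length >= 3).
#' @param fs sampling rate (Hz); required when `min_distance_ms > 0`.
#' @param min_distance_ms minimum distance between retained peaks.
#' @return Integer vector of 1-based peak sample indices, in ascending
#'   order.
#' @export
gfp_peaks <- function(gfp_series, fs = NULL, min_distance_ms = 10) {
  n <- length(gfp_series)
  if (n < 3) stop("series too short")
  d <- diff(gfp_series)
  idx <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  if (length(idx) == 0L || min_distance_ms <= 0) return(idx)
  if (is.null(fs)) stop("`fs` is required for a minimum peak distance")
  min_gap <- min_distance_ms / 1000 * fs
  keep <- logical(length(idx))
  taken <- integer(0)
  for (i in order(gfp_series[idx], decreasing = TRUE)) {
    if (!length(taken) || all(abs(idx[i] - taken) >= min_gap)) {
      keep[i] <- TRUE
      taken <- c(taken, idx[i])
    }
  }
  sort(idx[keep])
}

#' Polarity-invariant (modified) K-means clustering of scalp maps
#'
#' Clusters maps ignoring polarity: assignment maximizes squared spatial
#' correlation with the templates, and each template update is the first
#' principal axis of its assigned maps (so a map and its negation are
#' equivalent). Multiple restarts keep the solution with the highest global
#' explained variance (GEV). Deterministic for a fixed seed.
#'
#' @param maps n_maps x channels matrix (typically GFP-peak maps).
#' @param k number of templates.
#' @param n_init random restarts.
#' @param max_iter iteration cap per restart.
#' @param tol convergence tolerance on GEV improvement.
#' @param seed integer seed for the restarts.
#' @return A list of class `microstate_solution`: `templates`
#'   (k x channels, average-referenced unit-norm), `labels` (per input
#'   map), `gev`.
#' @export
modified_kmeans <- function(maps, k = 4, n_init = 20, max_iter = 500,
                            tol = 1e-7, seed = 1L) {
  maps <- as.matrix(maps)
  if (nrow(maps) < k) stop("fewer maps than clusters")
  v <- maps - rowMeans(maps)
  if (all(abs(v) < 1e-12)) stop("degenerate all-identical maps")
  vt <- t(v) # channels x n
  ss_tot <- sum(v^2)
  run_once <- function() {
    templ <- normalize_maps(v[sample.int(nrow(v), k), , drop = FALSE])
    gev_prev <- -Inf
    labels <- NULL
    for (it in seq_len(max_iter)) {
      a <- templ %*% vt # k x n projections
      labels <- max.col(t(a^2), ties.method = "first")
      for (c_i in seq_len(k)) {
        members <- which(labels == c_i)
        if (!length(members)) {
          templ[c_i, ] <- normalize_maps(v[sample.int(nrow(v), 1L), ,
                                           drop = FALSE])
          next
        }
        sub <- vt[, members, drop = FALSE]
        ev <- eigen(tcrossprod(sub), symmetric = TRUE)
        templ[c_i, ] <- ev$vectors[, 1L]
      }
      templ <- normalize_maps(templ)
      a <- templ %*% vt
      gev <- sum(a[cbind(max.col(t(a^2), ties.method = "first"),
                         seq_len(ncol(a)))]^2) / ss_tot
      if (gev - gev_prev < tol) break
      gev_prev <- gev
    }
    a <- templ %*% vt
    labels <- max.col(t(a^2), ties.method = "first")
    gev <- sum(a[cbind(labels, seq_len(ncol(a)))]^2) / ss_tot
    list(templates = templ, labels = labels, gev = gev)
  }
  local_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      sol <- run_once()
      if (is.null(best) || sol$gev > best$gev) best <- sol
    }
    structure(best, class = "microstate_solution")
  })
}

#' @export
print.microstate_solution <- function(x, ...) {
  cat(sprintf("<microstate_solution> k=%d templates x %d channels, GEV=%.3f\n",
              nrow(x$templates), ncol(x$templates), x$gev))
  invisible(x)
}

#' Group-level microstate templates
#'
#' Second-level polarity-invariant K-means over the pooled subject-level
#' template maps.
#'
#' @param per_subject_templates list of k_i x channels template matrices
#'   (>= 2 subjects).
#' @param k number of group templates.
#' @param seed integer seed.
#' @return A `microstate_solution` over the pooled templates.
#' @export
group_templates <- function(per_subject_templates, k = 4, seed = 1L) {
  if (length(per_subject_templates) < 2) stop("need >= 2 subjects")
  pooled <- do.call(rbind, per_subject_templates)
  modified_kmeans(pooled, k = k, n_init = 20, seed = seed)
}

#' Canonical microstate topographies A-D
#'
#' Analytic dipolar patterns on standard 10-20 coordinates realizing the
#' four classic orientations: A, a left-posterior to right-anterior
#' gradient; B, a right-posterior to left-anterior gradient; C, an
#' anterior-posterior gradient; D, a central maximum. Average-referenced
#' and unit-normalized; polarity is non-informative. Users with other
#' montages can supply their own canonical set to [label_templates()].
#'
#' @param channel_labels montage labels; must be a subset of the standard
#'   19-channel 10-20 set.
#' @return 4 x channels matrix with rownames `A`-`D`.
#' @export
canonical_microstate_maps <- function(channel_labels = standard_1020()) {
  xy <- standard_1020_xy()
  unknown <- setdiff(channel_labels, rownames(xy))
  if (length(unknown))
    stop("no canonical coordinates for channels: ",
         paste(unknown, collapse = ", "))
  xy <- xy[channel_labels, , drop = FALSE]
  maps <- rbind(
    A = xy[, "x"] + xy[, "y"],
    B = -xy[, "x"] + xy[, "y"],
    C = xy[, "y"],
    D = 1 - (xy[, "x"]^2 + xy[, "y"]^2))
  out <- normalize_maps(maps)
  rownames(out) <- c("A", "B", "C", "D")
  colnames(out) <- channel_labels
  out
}

#' Label templates against a canonical set
#'
#' Finds the assignment of estimated templates to canonical classes that
#' maximizes the total absolute spatial correlation, by exhaustive search
#' over all k! permutations (k = 4 gives 24).
#'
#' @param templates k x channels estimated templates.
#' @param canonical_set k x channels canonical maps with rownames giving
#'   the class names; defaults to [canonical_microstate_maps()] on the
#'   template montage when it has 19 channels.
#' @return Character vector of class names, one per template row, with
#'   attribute `total_correlation`.
#' @export
label_templates <- function(templates, canonical_set = NULL) {
  templates <- normalize_maps(templates)
  if (is.null(canonical_set)) {
    if (ncol(templates) != 19)
      stop("supply a canonical_set matching this montage")
    canonical_set <- canonical_microstate_maps()
  }
  if (ncol(canonical_set) != ncol(templates))
    stop("montage mismatch between templates and canonical set")
  canonical_set_n <- normalize_maps(canonical_set)
  k <- nrow(templates)
  cors <- abs(templates %*% t(canonical_set_n))
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p)
    sum(cors[cbind(seq_len(k), p)]), numeric(1))
  best <- perms[[which.max(scores)]]
  out <- rownames(canonical_set)[best]
  attr(out, "total_correlation") <- max(scores)
  out
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L))
    for (pos in 0:(k - 1L))
      out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}

#' Backfit templates to a recording
#'
#' Assigns every sample the template with the highest absolute spatial
#' correlation to its (average-referenced) map. Samples with zero GFP are
#' unassigned (`NA`). Optional temporal smoothing reassigns runs shorter
#' than `min_duration_ms` sample-by-sample to whichever flanking label
#' correlates better (default off).
#'
#' @param recording an [eeg_recording()].
#' @param templates k x channels template maps.
#' @param min_duration_ms minimum accepted run length for smoothing; 0
#'   disables.
#' @return Integer vector of per-sample template indices (1-based, `NA` for
#'   unassigned).
#' @export
backfit <- function(recording, templates, min_duration_ms = 0) {
  templates <- normalize_maps(templates)
  vt <- average_reference(recording$data)
  nrm <- sqrt(colSums(vt^2))
  a <- abs_spatial_corr(templates, vt)
  labels <- max.col(t(a), ties.method = "first")
  labels[nrm == 0] <- NA_integer_
  if (min_duration_ms > 0) {
    min_len <- round(min_duration_ms / 1000 * recording$fs)
    # repeatedly merge the shortest sub-threshold run, as a whole, into the
    # flanking label with the higher mean correlation; each merge reduces
    # the run count, so this terminates with all runs >= min_len or a
    # single run left
    repeat {
      r <- rle(labels)
      if (length(r$values) <= 1L) break
      short <- which(r$lengths < min_len & !is.na(r$values))
      if (!length(short)) break
      s_i <- short[which.min(r$lengths[short])]
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      left <- if (s_i > 1L) r$values[s_i - 1L] else NA_integer_
      right <- if (s_i < length(r$values)) r$values[s_i + 1L] else NA_integer_
      cand <- unique(stats::na.omit(c(left, right)))
      if (!length(cand)) break
      seg <- starts[s_i]:ends[s_i]
      score <- vapply(cand, function(ci) mean(a[ci, seg]), numeric(1))
      labels[seg] <- cand[which.max(score)]
    }
    if (length(unique(stats::na.omit(labels))) == 1L)
      attr(labels, "degenerate_smoothing") <- TRUE
  }
  labels
}

#' Microstate statistics
#'
#' Run-based summary of a label sequence: per state, occurrence (runs per
#' second), mean duration (total dwell samples per run, in ms) and coverage
#' (fraction of all samples). Coverages sum to 1 when no sample is
#' unassigned, and `occurrence x duration ~ coverage` up to run-boundary
#' edge effects.
#'
#' @param labels integer label sequence (e.g. from [backfit()]); `NA`
#'   samples are unassigned.
#' @param fs sampling rate (Hz).
#' @param k number of states; inferred from the labels if missing.
#' @param state_names optional names, e.g. from [label_templates()].
#' @return A data.frame with columns `state`, `occurrence` (1/s),
#'   `duration` (ms), `coverage`.
#' @export
microstate_stats <- function(labels, fs, k = NULL, state_names = NULL) {
  if (length(labels) == 0L) stop("empty label sequence")
  if (is.null(k)) k <- max(labels, na.rm = TRUE)
  total_s <- length(labels) / fs
  r <- rle(as.integer(labels))
  out <- data.frame(state = seq_len(k), occurrence = 0, duration = NA_real_,
                    coverage = 0)
  for (s_i in seq_len(k)) {
    runs <- which(r$values == s_i & !is.na(r$values))
    n_runs <- length(runs)
    n_samp <- sum(r$lengths[runs])
    out$occurrence[s_i] <- n_runs / total_s
    out$duration[s_i] <- if (n_runs > 0) n_samp / n_runs / fs * 1000 else NA
    out$coverage[s_i] <- n_samp / length(labels)
  }
  if (!is.null(state_names)) out$state <- state_names[out$state]
  out
}

#' Single-recording microstate pipeline
#'
#' GFP-peak extraction, polarity-invariant K-means on the peak maps,
#' canonical A-D labeling, whole-recording backfit and run statistics.
#'
#' @param recording an [eeg_recording()].
#' @param k number of microstate classes.
#' @param templates optional fixed templates (skips clustering).
#' @param canonical_set canonical maps for labeling; `NULL` uses the
#'   standard set when the montage allows, otherwise states are numbered.
#' @param n_init restarts for the clustering.
#' @param seed integer seed.
#' @param min_duration_ms backfit smoothing (0 = off).
#' @return A list with `solution` (or `NULL` when templates were given),
#'   `names`, `labels`, `stats` (a [microstate_stats()] frame).
#' @export
microstate_pipeline <- function(recording, k = 4, templates = NULL,
                                canonical_set = NULL, n_init = 20,
                                seed = 1L, min_duration_ms = 0) {
  rec <- average_reference(recording)
  solution <- NULL
  if (is.null(templates)) {
    g <- gfp(rec, reference = "none")
    pk <- gfp_peaks(g, rec$fs)
    maps <- t(rec$data[, pk, drop = FALSE])
    solution <- modified_kmeans(maps, k = k, n_init = n_init, seed = seed)
    templates <- solution$templates
  }
  nms <- if (ncol(templates) == 19 || !is.null(canonical_set))
    label_templates(templates, canonical_set) else as.character(seq_len(k))
  labels <- backfit(rec, templates, min_duration_ms)
  st <- microstate_stats(labels, rec$fs, k = nrow(templates),
                         state_names = nms)
  list(solution = solution, names = nms, labels = labels, stats = st)
}

#' Microstate feature rows for a recording
#'
#' @inheritParams microstate_pipeline
#' @return A data.frame with columns `channel` (`"global"`), `feature`
#'   (`ms<X>_occurrence` / `_duration` / `_coverage`) and `value`.
#' @export
microstate_features <- function(recording, k = 4, templates = NULL,
                                seed = 1L) {
  res <- microstate_pipeline(recording, k = k, templates = templates,
                             seed = seed)
  st <- res$stats
  data.frame(
    channel = "global",
    feature = c(paste0("ms", st$state, "_occurrence"),
                paste0("ms", st$state, "_duration"),
                paste0("ms", st$state, "_coverage")),
    value = c(st$occurrence, st$duration, st$coverage))
}

#' Write / read microstate templates
#'
#' Templates are stored as a channels x k tab-separated matrix whose header
#' line carries the state names (e.g. `A`-`D`).
#'
#' @param templates k x channels template matrix.
#' @param names state names, one per template row.
#' @param path output path.
#' @return `write_templates` invisibly returns `path`; `read_templates`
#'   returns a list with `templates` (k x channels) and `names`.
#' @export
write_templates <- function(templates, names, path) {
  stopifnot(nrow(templates) == length(names))
  out <- t(templates)
  colnames(out) <- names
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  m <- as.matrix(read.delim(path, header = TRUE, check.names = FALSE))
  list(templates = t(unname(m)), names = colnames(m))
}
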