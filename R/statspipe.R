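#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment: with sorted p-values `p_(1) <= ... <= p_(m)`, the
#' adjusted value of `p_(i)` is `min over j >= i of p_(j) * m / j`, capped
#' at 1; hypotheses with adjusted p `<= q` are rejected.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return A list with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))$reject
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(ranked)))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Significance stars
#'
#' Four-level convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001; empty string otherwise.
#'
#' @param p numeric vector of (adjusted) p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else ""
  }, character(1))
}

#' Group comparisons over a feature table
#'
#' Runs the declared two-group test for every `(feature, channel)` cell of
#' a long-format feature table and applies Benjamini-Hochberg FDR across
#' the whole family of comparisons (all channels x features passed in; the
#' family is whatever table the caller scopes).
#'
#' Paired designs match observations by subject and use the paired t-test
#' or Wilcoxon signed-rank test; independent designs use the two-sample
#' t-test (Welch) or Wilcoxon rank-sum test.
#'
#' @param feature_table data.frame with columns `subject`, `state`,
#'   `channel`, `feature`, `value`.
#' @param states length-2 character vector: the two state labels to
#'   compare, in order (statistics are oriented `states[1] - states[2]`).
#' @param paired logical.
#' @param test `"t"` or `"wilcoxon"`.
#' @param q FDR level.
#' @return A data.frame with one row per comparison: `feature`, `channel`,
#'   `group1`, `group2`, `test`, `statistic`, `p`, `p_adjusted`, `stars`,
#'   `reject`.
#' @export
compare_groups <- function(feature_table, states, paired = FALSE,
                           test = c("t", "wilcoxon"), q = 0.05) {
  test <- match.arg(test)
  ft <- feature_table[feature_table$state %in% states, ]
  cells <- unique(ft[, c("feature", "channel")])
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    sub <- ft[ft$feature == cells$feature[r] & ft$channel == cells$channel[r], ]
    g1 <- sub[sub$state == states[1], ]
    g2 <- sub[sub$state == states[2], ]
    if (nrow(g1) < 2 || nrow(g2) < 2)
      stop("fewer than 2 observations per group for ", cells$feature[r])
    if (paired) {
      common <- intersect(g1$subject, g2$subject)
      if (length(common) < 2)
        stop("paired design with unmatched subjects for ", cells$feature[r])
      x <- g1$value[match(common, g1$subject)]
      y <- g2$value[match(common, g2$subject)]
      res <- if (test == "t") t.test(x, y, paired = TRUE)
             else wilcox.test(x, y, paired = TRUE, exact = FALSE)
      tname <- if (test == "t") "paired t" else "wilcoxon signed-rank"
    } else {
      x <- g1$value; y <- g2$value
      res <- if (test == "t") t.test(x, y)
             else wilcox.test(x, y, exact = FALSE)
      tname <- if (test == "t") "independent t" else "wilcoxon rank-sum"
    }
    rows[[r]] <- data.frame(
      feature = cells$feature[r], channel = cells$channel[r],
      group1 = states[1], group2 = states[2], test = tname,
      statistic = unname(res$statistic), p = res$p.value)
  }
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, q)
  out$p_adjusted <- fdr$adjusted
  out$stars <- significance_stars(out$p_adjusted)
  out$reject <- fdr$reject
  out
}

#' Write a synthetic cohort to canonical fixture files
#'
#' Lays a [sim_cohort()] result out on disk: per subject, a
#' `rest_<state>_<id>.tsv` resting recording, an `ms_<state>_<id>.tsv`
#' microstate recording and an `epochs_<state>_<id>.tsv` evoked file (each
#' with its JSON sidecar), for whichever components the cohort carries.
#'
#' @param cohort a [sim_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (state in names(cohort)) for (entry in cohort[[state]]) {
    tag <- sprintf("%s_%s", state, entry$subject_id)
    if (!is.null(entry$rest))
      write_recording(entry$rest, file.path(dir, sprintf("rest_%s.tsv", tag)))
    if (!is.null(entry$microstate))
      write_recording(entry$microstate$recording,
                      file.path(dir, sprintf("ms_%s.tsv", tag)))
    if (!is.null(entry$evoked))
      write_epochs(entry$evoked, file.path(dir, sprintf("epochs_%s.tsv", tag)))
  }
  invisible(dir)
}

#' End-to-end feature pipeline
#'
#' Reads every canonical fixture in `input_dir` (file-name prefixes select
#' the family: `rest_*` spontaneous recordings, `ms_*` microstate
#' recordings, `epochs_*` evoked epochs), computes the enabled feature
#' families, optionally writes the feature table, and runs the declared
#' group contrasts with FDR correction. Per-subject failures are logged and
#' skipped (fail-soft); the `status` element is non-zero if any stage
#' failed.
#'
#' Spontaneous families are computed per subject. Microstate templates are
#' estimated at the group level within each state (subject-level clustering
#' of GFP-peak maps, then a second-level clustering), labeled against the
#' canonical A-D maps, and backfitted per subject.
#'
#' @param config an [analysis_config()].
#' @param input_dir directory of canonical fixtures.
#' @param out_dir optional output directory for `features.csv` and
#'   `comparisons.csv`.
#' @param families subset of `c("spectral", "aperiodic", "complexity",
#'   "network", "microstate", "evoked")`.
#' @param contrasts optional list of contrast declarations, each a list
#'   with `states` (length 2), `paired`, `test`.
#' @param graph_densities densities for the network family (default: the
#'   config's `graph_density` only, for speed; pass
#'   `config$density_sweep` for the full sweep).
#' @return A list with `features` (long data.frame), `comparisons` (or
#'   `NULL`), `errors` (character), `status` (0 = clean, 1 = failures).
#' @export
run_pipeline <- function(config, input_dir, out_dir = NULL,
                         families = c("spectral", "aperiodic", "complexity",
                                      "network", "microstate", "evoked"),
                         contrasts = NULL,
                         graph_densities = config$graph_density) {
  files <- list.files(input_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no canonical fixtures found in ", input_dir)
  errors <- character(0)
  feats <- list()
  note <- function(ft, rec) {
    if (is.null(ft)) return()
    ft$subject <- rec$subject_id
    ft$state <- rec$state_label
    feats[[length(feats) + 1L]] <<- ft[, c("subject", "state", "channel",
                                           "feature", "value")]
  }
  rest_files <- files[grepl("^rest_", basename(files))]
  ms_files <- files[grepl("^ms_", basename(files))]
  ep_files <- files[grepl("^epochs_", basename(files))]
  for (f in rest_files) {
    rec <- try(read_recording(f), silent = TRUE)
    if (inherits(rec, "try-error")) {
      errors <- c(errors, sprintf("%s: %s", basename(f), attr(rec, "condition")$message))
      next
    }
    for (fam in intersect(families, c("spectral", "aperiodic", "complexity",
                                      "network"))) {
      ft <- tryCatch(switch(fam,
        spectral = band_features(rec, config),
        aperiodic = aperiodic_features(rec, config),
        complexity = complexity_features(rec),
        network = network_features(rec, config,
                                   densities = graph_densities)),
        error = function(e) {
          errors <<- c(errors, sprintf("%s [%s/%s]: %s", basename(f),
                                       rec$subject_id, fam, e$message))
          NULL
        })
      note(ft, rec)
    }
  }
  if ("microstate" %in% families && length(ms_files)) {
    ms_recs <- list()
    for (f in ms_files) {
      rec <- try(read_recording(f), silent = TRUE)
      if (inherits(rec, "try-error")) {
        errors <- c(errors, sprintf("%s: %s", basename(f),
                                    attr(rec, "condition")$message))
        next
      }
      ms_recs[[length(ms_recs) + 1L]] <- rec
    }
    states <- unique(vapply(ms_recs, `[[`, "", "state_label"))
    for (st in states) {
      grp <- Filter(function(r) r$state_label == st, ms_recs)
      ft <- tryCatch({
        subj_templates <- lapply(grp, function(r) {
          r <- average_reference(r)
          pk <- gfp_peaks(gfp(r, "none"), r$fs)
          modified_kmeans(t(r$data[, pk, drop = FALSE]),
                          k = config$microstate_k, n_init = 5,
                          seed = config$seed)$templates
        })
        templ <- if (length(grp) > 1)
          group_templates(subj_templates, k = config$microstate_k,
                          seed = config$seed)$templates
          else subj_templates[[1]]
        nms <- label_templates(templ)
        for (r in grp) {
          st_df <- microstate_stats(backfit(r, templ), r$fs,
                                    k = config$microstate_k,
                                    state_names = nms)
          note(data.frame(channel = "global",
                          feature = c(paste0("ms", st_df$state, "_occurrence"),
                                      paste0("ms", st_df$state, "_duration"),
                                      paste0("ms", st_df$state, "_coverage")),
                          value = c(st_df$occurrence, st_df$duration,
                                    st_df$coverage)), r)
        }
        NULL
      }, error = function(e) {
        errors <<- c(errors, sprintf("microstate group %s: %s", st, e$message))
        NULL
      })
    }
  }
  if ("evoked" %in% families) for (f in ep_files) {
    side <- jsonlite::read_json(sidecar_path_for(f), simplifyVector = TRUE)
    ep <- try(read_epochs(f), silent = TRUE)
    if (inherits(ep, "try-error")) {
      errors <- c(errors, sprintf("%s: %s", basename(f),
                                  attr(ep, "condition")$message))
      next
    }
    meta <- parse_fixture_name(basename(f))
    ft <- tryCatch(evoked_features(ep, window = config$evoked_window),
                   error = function(e) {
                     errors <<- c(errors, sprintf("%s: %s", basename(f),
                                                  e$message))
                     NULL
                   })
    note(ft, list(subject_id = meta$subject, state_label = meta$state))
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    stop("pipeline produced no features")
  comparisons <- NULL
  if (!is.null(contrasts)) {
    comparisons <- do.call(rbind, lapply(contrasts, function(ct)
      compare_groups(features, states = ct$states,
                     paired = isTRUE(ct$paired),
                     test = ct$test %||% "t", q = config$fdr_q)))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    if (!is.null(comparisons))
      write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                row.names = FALSE)
  }
  list(features = features, comparisons = comparisons, errors = errors,
       status = as.integer(length(errors) > 0))
}

parse_fixture_name <- function(fname) {
  stem <- sub("\\.tsv$", "", fname)
  parts <- strsplit(stem, "_")[[1]]
  if (length(parts) >= 3)
    list(state = parts[2], subject = paste(parts[-(1:2)], collapse = "_"))
  else list(state = "unknown", subject = stem)
}
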