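test_that("GFP is the spatial SD and scales homogeneously", {
  # identical values per sample vanish under the average reference
  m <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4, byrow = FALSE)
  expect_equal(gfp(m), rep(0, 3))
  withr::with_seed(301, x <- matrix(rnorm(40), 4))
  expect_equal(gfp(3 * x), 3 * gfp(x))
  expect_error(gfp(matrix(1, 1, 10)), "2 channels")
})

test_that("GFP peaks are strict local maxima with a distance constraint", {
  expect_equal(gfp_peaks(c(0, 1, 0, 1, 0), min_distance_ms = 0), c(2L, 4L))
  expect_length(gfp_peaks(1:10, min_distance_ms = 0), 0L)

  # 5 Hz sinusoidal GFP over 10 s: one peak per cycle (phase offset keeps
  # sample pairs from tying exactly at the crest, where a strict local
  # maximum would be undefined)
  g <- sin(2 * pi * 5 * seq_len(2500) / 250 + 0.3) + 2
  pk <- gfp_peaks(g, fs = 250)
  expect_lt(abs(length(pk) - 50), 2)

  # minimum-distance constraint suppresses the weaker of two close peaks
  gg <- c(0, 1, 0, 0.9, 0)
  expect_equal(gfp_peaks(gg, fs = 1000, min_distance_ms = 10), 2L)
})

test_that("modified K-means recovers noiseless templates up to sign", {
  truth <- canonical_microstate_maps()
  withr::with_seed(302, {
    lab <- sample.int(4, 600, replace = TRUE)
    signs <- sample(c(-1, 1), 600, replace = TRUE)
    amps <- runif(600, 0.5, 2)
  })
  maps <- truth[lab, ] * signs * amps
  sol <- modified_kmeans(maps, k = 4, n_init = 10, seed = 1)
  cors <- abs(sol$templates %*% t(truth))
  expect_true(all(apply(cors, 1, max) > 0.999))
  expect_gt(sol$gev, 0.999)

  # k = 1 is the first principal axis of all maps
  sol1 <- modified_kmeans(maps, k = 1, n_init = 2, seed = 1)
  pc1 <- eigen(crossprod(maps - rowMeans(maps)))$vectors[, 1]
  expect_gt(abs(sum(sol1$templates[1, ] * pc1 / sqrt(sum(pc1^2)))), 0.999)

  # global sign flip leaves templates (up to sign) and gev unchanged
  sol_f <- modified_kmeans(-maps, k = 4, n_init = 10, seed = 1)
  expect_equal(sol_f$gev, sol$gev, tolerance = 1e-9)
  expect_true(all(abs(diag(abs(sol_f$templates %*% t(sol$templates))) - 1)
                  < 1e-6))
  expect_error(modified_kmeans(maps[1:2, ], k = 4), "fewer maps")
  expect_error(modified_kmeans(matrix(1, 10, 5), k = 2), "degenerate")
})

test_that("group templates pool subject templates polarity-invariantly", {
  truth <- canonical_microstate_maps()
  subj <- list(truth, truth, truth)
  g1 <- group_templates(subj, k = 4, seed = 2)
  expect_true(all(apply(abs(g1$templates %*% t(truth)), 1, max) > 0.999))

  flipped <- list(truth, -truth, truth)
  g2 <- group_templates(flipped, k = 4, seed = 2)
  expect_true(all(apply(abs(g2$templates %*% t(truth)), 1, max) > 0.999))

  # noisy subjects: group maps at least as close to truth as the median
  # subject's own templates
  withr::with_seed(303, {
    noisy <- lapply(1:12, function(i) truth + matrix(rnorm(76, sd = 0.12),
                                                     4))
  })
  gn <- group_templates(noisy, k = 4, seed = 3)
  close_g <- mean(apply(abs(gn$templates %*% t(truth)), 1, max))
  close_s <- vapply(noisy, function(tm)
    mean(apply(abs(normalize_maps_for_test(tm) %*% t(truth)), 1, max)),
    numeric(1))
  expect_gte(close_g, stats::median(close_s))
  expect_error(group_templates(list(truth), k = 4), "2 subjects")
})

test_that("canonical labeling recovers shuffles, signs and noisy maps", {
  truth <- canonical_microstate_maps()
  shuffle <- c(3, 1, 4, 2)
  expect_equal(label_templates(truth[shuffle, ]),
               c("C", "A", "D", "B"), ignore_attr = TRUE)
  expect_equal(label_templates(-truth[shuffle, ]),
               c("C", "A", "D", "B"), ignore_attr = TRUE)

  withr::with_seed(304, {
    hits <- vapply(1:200, function(i) {
      noisy <- truth + matrix(rnorm(76, sd = sqrt(mean(truth^2)) / 5), 4)
      all(label_templates(noisy) == c("A", "B", "C", "D"))
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
  expect_error(label_templates(truth[, 1:10]), "canonical_set matching")
})

test_that("backfitting is exact in the noiseless limit", {
  truth <- canonical_microstate_maps()
  rec1 <- eeg_recording(outer(truth[2, ], abs(sin(seq_len(500) / 10)) + 0.2),
                        250, channel_labels = colnames(truth))
  expect_true(all(backfit(rec1, truth) == 2L))

  ms <- sim_microstate_eeg(truth, 0.08, 250, 20, snr = Inf, seed = 305)
  lab <- backfit(ms$recording, truth)
  expect_equal(mean(lab == ms$labels), 1)

  # smoothing window larger than every run collapses to one label
  lab_s <- backfit(ms$recording, truth, min_duration_ms = 5000)
  expect_true(attr(lab_s, "degenerate_smoothing"))
  expect_equal(length(unique(lab_s)), 1L)
})

test_that("microstate statistics match exact run arithmetic", {
  # alternating A/B every 100 ms at 1 kHz for 10 s
  lab <- rep(rep(1:2, each = 100), 50)
  st <- microstate_stats(lab, fs = 1000)
  expect_equal(st$occurrence, c(5, 5))
  expect_equal(st$duration, c(100, 100))
  expect_equal(st$coverage, c(0.5, 0.5))

  one <- microstate_stats(rep(3L, 10000), fs = 1000, k = 3)
  expect_equal(one$occurrence[3], 0.1)
  expect_equal(one$duration[3], 10000)
  expect_equal(one$coverage[3], 1)

  withr::with_seed(306, lab_r <- sample.int(4, 5000, replace = TRUE))
  expect_equal(sum(microstate_stats(lab_r, 250)$coverage), 1)
  # occurrence x duration ~ coverage
  st_r <- microstate_stats(lab_r, 250)
  expect_equal(st_r$occurrence * st_r$duration / 1000, st_r$coverage,
               tolerance = 0.01)
  expect_error(microstate_stats(integer(0), 250), "empty")
})

test_that("the full pipeline is polarity-invariant and gev grows with k", {
  truth <- canonical_microstate_maps()
  ms <- sim_microstate_eeg(truth, 0.08, 250, 30, snr = 5, seed = 307)
  res <- microstate_pipeline(ms$recording, seed = 5, n_init = 5)
  neg <- ms$recording
  neg$data <- -neg$data
  res_neg <- microstate_pipeline(neg, seed = 5, n_init = 5)
  expect_equal(res_neg$stats$occurrence, res$stats$occurrence)
  expect_equal(res_neg$stats$duration, res$stats$duration)
  expect_equal(res_neg$stats$coverage, res$stats$coverage)

  rec <- average_reference(ms$recording)
  pk <- gfp_peaks(gfp(rec, "none"), 250)
  maps <- t(rec$data[, pk])
  gevs <- vapply(1:6, function(k)
    modified_kmeans(maps, k = k, n_init = 3, seed = 1)$gev, numeric(1))
  expect_true(all(diff(gevs) > -1e-9))
})

test_that("dwell-time recovery stays within 12.5% at SNR 5", {
  truth <- canonical_microstate_maps()
  rel_err <- vapply(1:3, function(s) {
    ms <- sim_microstate_eeg(truth, 0.08, 250, 60, snr = 5, seed = 310 + s)
    res <- microstate_pipeline(ms$recording, seed = 1, n_init = 5)
    mean(res$stats$duration) / 80 - 1
  }, numeric(1))
  expect_lt(max(abs(rel_err)), 0.125)
})

test_that("template export round-trips with state names", {
  truth <- canonical_microstate_maps()
  path <- file.path(tempdir(), "templates.tsv")
  write_templates(truth, c("A", "B", "C", "D"), path)
  back <- read_templates(path)
  expect_equal(back$names, c("A", "B", "C", "D"))
  expect_equal(back$templates, unname(truth), tolerance = 1e-12)
})
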