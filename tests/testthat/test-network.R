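test_that("PCMI attains the entropy ceiling for copies and zero for noise", {
  withr::with_seed(201, {
    x <- rnorm(5e4)
    y <- rnorm(5e4)
  })
  self <- pcmi_pair(x, x)
  h <- permutation_entropy(x, 3) * log2(factorial(3))
  expect_lt(abs(as.numeric(self) - h), 0.01)
  expect_lte(as.numeric(pcmi_pair(x, y)), 0.01)

  # 5-sample delayed copy: maximizing lag 5, value near the ceiling
  yd <- c(rep(0.123, 5), x)[seq_along(x)]
  v <- pcmi_pair(yd, x, max_lag = 10)
  expect_equal(attr(v, "lag"), 5L)
  expect_lt(abs(as.numeric(v) - h) / h, 0.05)

  # exact argument symmetry
  expect_equal(as.numeric(pcmi_pair(x, yd, max_lag = 10)), as.numeric(v))
  expect_error(pcmi_pair(x, y[1:10]), "equal length")
})

test_that("PCMI increases with coupling strength", {
  mi_at <- function(s, seed) {
    spec <- synthetic_spec(2, 40, 100, chi = 0.5,
                           coupling = data.frame(i = 1, j = 2, strength = s,
                                                 delay = 2),
                           seed = seed)
    rec <- sim_recording(spec)
    as.numeric(pcmi_pair(rec$data[1, ], rec$data[2, ]))
  }
  curve <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s)
    mean(vapply(1:5, function(sd) mi_at(s, 300 + sd), numeric(1))),
    numeric(1))
  expect_true(all(diff(curve) > 0))
})

test_that("PLI vanishes at zero lag and saturates at a quarter cycle", {
  fs <- 250
  t <- seq_len(1e4) / fs
  x <- sin(2 * pi * 10 * t)
  expect_equal(pli_pair(x, x, c(8, 13), fs), 0)
  y <- sin(2 * pi * 10 * t - pi / 2)
  expect_gt(pli_pair(x, y, c(8, 13), fs), 0.99)
  withr::with_seed(202, {
    a <- rnorm(1e5)
    b <- rnorm(1e5)
  })
  expect_lt(pli_pair(a, b, c(8, 13), fs), 0.05)
})

test_that("connectivity matrices are symmetric with informative structure", {
  spec <- synthetic_spec(3, 40, 100, chi = 0.5,
                         coupling = data.frame(i = 1, j = 2, strength = 0.8,
                                               delay = 2),
                         channel_labels = c("a", "b", "c"), seed = 7)
  rec <- sim_recording(spec)
  conn <- connectivity_matrix(rec, "pcmi")
  m <- conn$matrix
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(which.max(m[upper.tri(m)]), 1L) # (a, b) is the strongest pair

  # duplicate channel attains the self-information ceiling
  rec2 <- eeg_recording(rbind(rec$data[1, ], rec$data[1, ], rec$data[3, ]),
                        100)
  m2 <- connectivity_matrix(rec2, "pcmi")$matrix
  h <- permutation_entropy(rec$data[1, ], 3) * log2(6)
  expect_lt(abs(m2[1, 2] - h), 0.01)

  # permuting channels permutes rows/columns consistently
  perm <- c(3, 1, 2)
  rec3 <- eeg_recording(rec$data[perm, ], 100,
                        channel_labels = rec$channel_labels[perm])
  m3 <- connectivity_matrix(rec3, "pcmi")$matrix
  expect_equal(m3, m[perm, perm])
})

test_that("proportional thresholding keeps the exact edge budget", {
  m <- random_weight_matrix(5, seed = 203)
  adj <- threshold_proportional(m, 0.05) # ceil(0.05 * 10) = 1 edge
  expect_equal(sum(adj) / 2, 1)
  expect_equal(sum(threshold_proportional(m, 1)) / 2, 10) # complete graph

  # against a full-sort oracle at density 0.5
  adj5 <- threshold_proportional(m, 0.5)
  w <- m[upper.tri(m)]
  cut <- sort(w, decreasing = TRUE)[5]
  expect_equal(adj5[upper.tri(adj5)] == 1, w >= cut)
  expect_warning(threshold_proportional(matrix(1, 3, 3) - diag(3), 0.5),
                 "tie-break")
})

test_that("graph metrics match hand-computed examples", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(clustering_coefficient(tri), 1)
  expect_equal(as.numeric(characteristic_path_length(tri)), 1)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  expect_equal(clustering_coefficient(path3), 0)

  g4 <- matrix(0, 4, 4)
  g4[1, 2] <- g4[1, 3] <- g4[2, 3] <- g4[3, 4] <- 1
  g4 <- g4 + t(g4)
  expect_equal(clustering_coefficient(g4), 7 / 12)

  path4 <- matrix(0, 4, 4)
  path4[1, 2] <- path4[2, 3] <- path4[3, 4] <- 1
  path4 <- path4 + t(path4)
  expect_equal(as.numeric(characteristic_path_length(path4)), 10 / 6)

  # two disjoint triangles: per-component L = 1 with a disconnection flag
  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- tri
  two_tri[4:6, 4:6] <- tri
  l2 <- characteristic_path_length(two_tri)
  expect_equal(as.numeric(l2), 1)
  expect_true(attr(l2, "disconnected"))
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "no edges")
})

test_that("graph metrics agree exactly with brute-force oracles", {
  withr::with_seed(204, {
    for (i in 1:25) {
      n <- sample(5:12, 1)
      a <- random_adjacency(n, runif(1, 0.2, 0.6), seed = 1000 + i)
      if (sum(a) == 0) next
      expect_equal(clustering_coefficient(a), bf_clustering(a))
      expect_equal(as.numeric(characteristic_path_length(a)),
                   bf_path_length(a))
    }
  })
})

test_that("small-worldness exceeds 1 for ring lattices with shortcuts", {
  g <- withr::with_seed(205,
    igraph::sample_smallworld(1, 100, 5, 0.1))
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  sig <- small_worldness(a, n_surrogates = 30, seed = 1)
  expect_gt(as.numeric(sig), 1.5)
  expect_identical(as.numeric(small_worldness(a, 10, seed = 3)),
                   as.numeric(small_worldness(a, 10, seed = 3)))
})

test_that("regional summaries recombine to the whole-brain mean", {
  labs <- standard_1020()
  rm19 <- assign_regions(labs)
  m <- matrix(0.3, 19, 19, dimnames = list(labs, labs))
  diag(m) <- 0
  reg <- regional_summary(m, rm19)
  expect_true(all(abs(reg - 0.3) < 1e-12))

  # pair-count-weighted mean of the within/between blocks equals W
  mw <- random_weight_matrix(19, seed = 206) / 100
  dimnames(mw) <- list(labs, labs)
  reg2 <- regional_summary(mw, rm19)
  sizes <- table(rm19)[c("frontal", "central", "parieto_occipital")]
  nf <- sizes[[1]]; ncn <- sizes[[2]]; np <- sizes[[3]]
  counts <- c(nf * (nf - 1) / 2, ncn * (ncn - 1) / 2, np * (np - 1) / 2,
              nf * ncn, ncn * np, nf * np)
  blocks <- reg2[c("F", "C", "PO", "F-C", "C-PO", "F-PO")]
  expect_equal(sum(blocks * counts) / sum(counts), reg2[["W"]])

  # frontal-only coupling fixture: F > PO with F-PO in between
  front <- which(rm19 == "frontal")
  cp <- data.frame(i = rep(front, each = 2)[1:10],
                   j = c(front[-1], front[1:4])[1:10],
                   strength = 0.9, delay = 2)
  cp <- cp[cp$i != cp$j, ]
  spec <- synthetic_spec(19, 40, 100, chi = 0.5, coupling = cp, seed = 11)
  conn <- connectivity_matrix(sim_recording(spec), "pcmi")
  reg3 <- regional_summary(conn, rm19)
  expect_gt(reg3[["F"]], reg3[["PO"]])
})
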