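# Independent brute-force oracles used to cross-check the package's
# implementations. These are deliberately naive (enumeration, direct
# definitions) and share no code with the functions they verify.

# AR(1) process with coefficient phi, innovations N(0, 1)
gen_ar1 <- function(n, phi, seed) {
  withr::with_seed(seed, {
    as.numeric(stats::filter(rnorm(n), phi, method = "recursive"))
  })
}

# random symmetric weight matrix with distinct entries, zero diagonal
random_weight_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- sample(seq_len(n * (n - 1) / 2))
    m + t(m)
  })
}

random_adjacency <- function(n, p, seed) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
    a + t(a)
  })
}

# per-node triangle counting straight from the definition
bf_clustering <- function(a) {
  n <- nrow(a)
  cs <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (x in nb) for (y in nb) if (x < y && a[x, y] > 0) tri <- tri + 1
    tri / (k * (k - 1) / 2)
  }, numeric(1))
  mean(cs)
}

# Floyd-Warshall all-pairs shortest paths; mean over finite pairs of the
# largest connected component
bf_path_length <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  # connected components from reachability
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(d[i, ])] <- cid
    }
  }
  sizes <- table(comp)
  big <- as.integer(names(sizes)[which.max(sizes)])
  idx <- which(comp == big)
  sub <- d[idx, idx]
  mean(sub[upper.tri(sub)])
}

# Exhaustive-history parse count, straight from the definition: each new
# component is the shortest prefix of the remainder that cannot be copied
# from the already-seen text (all positions before the component's end).
naive_lz76 <- function(s) {
  n <- length(s)
  is_sub <- function(pat, txt) {
    lp <- length(pat); lt <- length(txt)
    if (lp > lt) return(FALSE)
    for (st in seq_len(lt - lp + 1L))
      if (all(txt[st:(st + lp - 1L)] == pat)) return(TRUE)
    FALSE
  }
  cnt <- 0L
  i <- 1L
  while (i <= n) {
    l <- 1L
    while (i + l - 1L <= n &&
           is_sub(s[i:(i + l - 1L)], s[seq_len(i + l - 2L)])) l <- l + 1L
    cnt <- cnt + 1L
    i <- i + l
  }
  cnt
}

# literal step-up FDR: largest k with p_(k) <= k*q/m; adjusted by the
# explicit min-over-j definition
naive_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * q / m)
  reject_sorted <- rep(FALSE, m)
  if (length(ks)) reject_sorted[seq_len(max(ks))] <- TRUE
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  adjusted <- reject <- numeric(m)
  adjusted[o] <- adj_sorted
  reject[o] <- reject_sorted
  list(adjusted = adjusted, reject = as.logical(reject))
}

# quick synthetic preset recording at the cohort scale
preset_recording <- function(state, seed, duration_s = 60, fs = 100) {
  p <- state_preset(state)
  spec <- synthetic_spec(19, duration_s, fs, chi = p$chi,
                         oscillations = p$oscillations,
                         coupling = p$coupling, seed = seed)
  sim_recording(spec, state_label = p$state)
}

# average-reference + unit-norm rows (local copy for comparisons)
normalize_maps_for_test <- function(m) {
  m <- m - rowMeans(m)
  m / sqrt(rowSums(m^2))
}
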