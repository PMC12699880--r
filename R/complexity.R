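#' Median binarization
#'
#' Symbolizes a signal into a binary sequence: 1 where the sample is
#' strictly above the signal median, else 0 (ties at the median are 0 by
#' the strict-`>` rule).
#'
#' @param signal non-constant numeric vector.
#' @return An integer vector of 0/1 symbols with attributes `alphabet = 2`
#'   and `origin = "binarized"`.
#' @export
binarize_median <- function(signal) {
  if (var(signal) == 0) stop("constant signal")
  s <- as.integer(signal > median(signal))
  attr(s, "alphabet") <- 2L
  attr(s, "origin") <- "binarized"
  s
}

#' Lempel-Ziv (LZ76) complexity
#'
#' Counts the productions of the exhaustive-history parsing of a symbol
#' sequence (Lempel & Ziv 1976, Kaspar & Schuster recursion) and normalizes
#' by the asymptotic rate of a random sequence:
#' `c(n) * log(n) / (n * log(alphabet))`. Random sequences approach 1;
#' constant or periodic sequences approach 0. Invariant under strictly
#' monotone amplitude transforms when used with [binarize_median()].
#'
#' @param symbols integer symbol sequence (length >= 10), e.g. from
#'   [binarize_median()]; a numeric signal is binarized first.
#' @param alphabet alphabet size; inferred from the symbols if missing.
#' @return Normalized complexity (positive, ~1 for random sequences), with
#'   attribute `c_n` holding the raw production count.
#' @examples
#' lempel_ziv(binarize_median(rnorm(5000)))
#' @export
lempel_ziv <- function(symbols, alphabet = NULL) {
  if (is.double(symbols) && is.null(attr(symbols, "alphabet")))
    symbols <- binarize_median(symbols)
  n <- length(symbols)
  if (n < 10) stop("sequence too short (need >= 10 symbols)")
  if (is.null(alphabet))
    alphabet <- attr(symbols, "alphabet") %||% length(unique(symbols))
  if (alphabet < 2) stop("alphabet must have at least 2 symbols")
  cn <- .lz76_count_cpp(as.integer(symbols))
  out <- cn * log(n) / (n * log(alphabet))
  attr(out, "c_n") <- cn
  out
}

#' Ordinal (permutation) pattern symbolization
#'
#' Maps each embedding window of `m` samples at spacing `tau` to the
#' permutation that sorts its values, encoded as the 0-based lexicographic
#' rank of the stable argsort (ties broken by order of occurrence). The
#' resulting alphabet has `m!` symbols.
#'
#' @param signal numeric vector with `length > (m - 1) * tau + 1`.
#' @param m embedding dimension, 2-7.
#' @param tau embedding lag in samples.
#' @return Integer vector of pattern codes in `[0, m!)` with attributes
#'   `alphabet = factorial(m)`, `m`, `tau`, `origin = "ordinal"`, and
#'   `undersampled = TRUE` when `m! > length/10`.
#' @export
ordinal_patterns <- function(signal, m = 3, tau = 1) {
  if (m < 2 || m > 7) stop("`m` must be between 2 and 7")
  n <- length(signal)
  if (n < (m - 1) * tau + 1) stop("signal too short for this embedding")
  codes <- .ordinal_codes_cpp(as.numeric(signal), as.integer(m),
                              as.integer(tau))
  attr(codes, "alphabet") <- factorial(m)
  attr(codes, "m") <- m
  attr(codes, "tau") <- tau
  attr(codes, "origin") <- "ordinal"
  if (factorial(m) > length(codes) / 10) {
    attr(codes, "undersampled") <- TRUE
    warning("ordinal alphabet undersampled: m! > n/10")
  }
  codes
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution normalized by
#' `log(m!)`, in `[0, 1]`: 0 for a monotone ramp (a single pattern), 1 for
#' patterns uniform over the alphabet, as for white noise.
#'
#' @param x an [ordinal_patterns()] symbol sequence, or a numeric signal
#'   (symbolized with `m`, `tau` first).
#' @param m,tau embedding used when `x` is a raw signal.
#' @return Normalized entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(x, m = 3, tau = 1) {
  if (is.null(attr(x, "origin"))) x <- ordinal_patterns(x, m, tau)
  if (length(x) == 0L) stop("empty symbol sequence")
  k <- attr(x, "alphabet")
  p <- tabulate(x + 1L, nbins = k) / length(x)
  shannon_entropy(p) / log(k)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Disorder x disequilibrium (statistical) complexity
#'
#' The classic product measure of so-called type II complexity: normalized
#' Shannon disorder `H / log(N)` multiplied by the Euclidean disequilibrium
#' `D = sum((p_i - 1/N)^2)`, the squared distance of the distribution from
#' maximal disorder. It vanishes at both extremes -- the uniform
#' distribution (D = 0) and a degenerate one (H = 0) -- and peaks at
#' intermediate structure, unlike entropy-only (type I) measures that grow
#' monotonically with randomness.
#'
#' @param probabilities non-negative vector summing to 1 (tolerance 1e-9).
#' @return `H_norm * D` (non-negative scalar).
#' @examples
#' lmc_complexity(c(0.9, 0.1))
#' @export
lmc_complexity <- function(probabilities) {
  p <- as.numeric(probabilities)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("`probabilities` must be non-negative and sum to 1")
  n <- length(p)
  if (n < 2) return(0)
  h_norm <- shannon_entropy(p) / log(n)
  d <- sum((p - 1 / n)^2)
  h_norm * d
}

#' Complexity features of a recording
#'
#' Per-channel Lempel-Ziv complexity of the median-binarized signal,
#' permutation entropy, and the disorder x disequilibrium product of the
#' ordinal-pattern distribution (default m = 4 for the latter, following
#' common practice of a slightly richer alphabet for distribution-shape
#' measures).
#'
#' @param recording an [eeg_recording()].
#' @param m_pe,tau embedding for permutation entropy.
#' @param m_lmc embedding for the disorder x disequilibrium product.
#' @return A data.frame with columns `channel`, `feature` (`lzc`,
#'   `perm_entropy_m{m}`, `lmc_m{m}`) and `value`.
#' @export
complexity_features <- function(recording, m_pe = 3, tau = 1, m_lmc = 4) {
  rows <- lapply(seq_len(nrow(recording$data)), function(ch) {
    x <- recording$data[ch, ]
    lzc <- as.numeric(lempel_ziv(binarize_median(x)))
    pe <- permutation_entropy(x, m_pe, tau)
    codes <- ordinal_patterns(x, m_lmc, tau)
    p <- tabulate(codes + 1L, nbins = attr(codes, "alphabet")) / length(codes)
    data.frame(channel = recording$channel_labels[ch],
               feature = c("lzc", paste0("perm_entropy_m", m_pe),
                           paste0("lmc_m", m_lmc)),
               value = c(lzc, pe, lmc_complexity(p)))
  })
  do.call(rbind, rows)
}
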