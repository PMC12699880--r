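#' Colored (1/f^chi) noise
#'
#' Gaussian noise whose expected power spectral density falls off as
#' `1/f^chi`, built by frequency-domain amplitude shaping of white Gaussian
#' noise with random phases: the Fourier coefficients of a white draw are
#' scaled by `f^(-chi/2)` (DC zeroed) and transformed back. The result is
#' standardized to zero mean and unit variance; `chi = 0` reduces to white
#' noise.
#'
#' @param chi aperiodic exponent (>= 0); the expected log-log PSD slope is
#'   `-chi`.
#' @param n_samples length (>= 64).
#' @param fs sampling rate (Hz); sets the frequency grid only.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return Numeric vector of length `n_samples`.
#' @examples
#' x <- sim_colored_noise(1, 1024, 250, seed = 1)
#' @export
sim_colored_noise <- function(chi, n_samples, fs, seed = NULL) {
  if (chi < 0) stop("`chi` must be non-negative")
  if (n_samples < 64) stop("`n_samples` must be >= 64")
  local_seed(seed, {
    w <- rnorm(n_samples)
    shape_spectrum(w, fs, function(f) f^(-chi / 2))
  })
}

#' Narrowband oscillation
#'
#' Band-limited Gaussian process: white noise shaped in the frequency domain
#' by a Gaussian amplitude envelope centered on `center_freq` with standard
#' deviation `bandwidth / 2`, so at least 90% of the power lies inside
#' `center_freq +/- bandwidth`. `bandwidth = 0` degenerates to a pure
#' sinusoid with random phase. The signal is scaled so that its RMS equals
#' `amplitude / sqrt(2)` (the RMS of a sinusoid of that peak amplitude).
#'
#' @param center_freq center frequency (Hz), strictly below Nyquist.
#' @param bandwidth spectral width (Hz, >= 0).
#' @param amplitude peak-equivalent amplitude (microvolts); 0 gives zeros.
#' @param n_samples,fs length and sampling rate.
#' @param seed integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
sim_oscillation <- function(center_freq, bandwidth, amplitude, n_samples, fs,
                            seed = NULL) {
  if (center_freq <= 0 || center_freq >= fs / 2)
    stop("`center_freq` must lie in (0, fs/2)")
  if (amplitude == 0) return(numeric(n_samples))
  local_seed(seed, {
    if (bandwidth <= 0) {
      phase <- runif(1, 0, 2 * pi)
      return(amplitude * sin(2 * pi * center_freq * seq_len(n_samples) / fs +
                               phase))
    }
    w <- rnorm(n_samples)
    sig <- bandwidth / 2
    x <- shape_spectrum(w, fs, function(f) exp(-(f - center_freq)^2 / (2 * sig^2)))
    x * amplitude / sqrt(2)
  })
}

# Multiply the spectrum of x by env(|f|) (DC removed), return a real signal
# standardized to mean 0, sd 1.
shape_spectrum <- function(x, fs, env) {
  n <- length(x)
  f <- abs(seq(0, n - 1) - ifelse(seq(0, n - 1) >= n / 2, n, 0)) * fs / n
  a <- ifelse(f > 0, env(f), 0)
  a[!is.finite(a)] <- 0
  y <- Re(fft(fft(x) * a, inverse = TRUE) / n)
  y <- y - mean(y)
  s <- sd(y)
  if (s > 0) y <- y / s
  y
}

#' Synthetic recording specification
#'
#' Parameters of one synthetic resting-state EEG recording: per-channel
#' colored background noise, weighted narrowband oscillations, and optional
#' delayed pairwise coupling through shared latent components.
#'
#' @param n_channels number of channels.
#' @param duration_s,fs duration (s) and sampling rate (Hz).
#' @param chi aperiodic exponent of the per-channel background.
#' @param noise_amplitude background noise standard deviation (microvolts).
#' @param oscillations list of oscillation descriptors, each a list with
#'   `center_freq`, `bandwidth`, `amplitude` and `weights` (per-channel
#'   multipliers, recycled if scalar).
#' @param coupling data.frame with columns `i`, `j`, `strength` in `[0, 1]`
#'   and `delay` (samples): channels `i` and `j` share a latent colored
#'   component added at `strength` standard deviations, delayed at `j`.
#' @param channel_labels montage labels; defaults to [standard_1020()] when
#'   `n_channels == 19`.
#' @param seed integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels = 19, duration_s = 60, fs = 250,
                           chi = 1, noise_amplitude = 1,
                           oscillations = list(), coupling = NULL,
                           channel_labels = NULL, seed = 1L) {
  if (chi < 0) stop("`chi` must be non-negative")
  if (!is.null(coupling)) {
    stopifnot(all(c("i", "j", "strength", "delay") %in% names(coupling)))
    if (any(coupling$strength < 0 | coupling$strength > 1))
      stop("coupling strengths must lie in [0, 1]")
  }
  if (is.null(channel_labels))
    channel_labels <- if (n_channels == 19) standard_1020()
                      else paste0("ch", seq_len(n_channels))
  structure(list(n_channels = n_channels, duration_s = duration_s, fs = fs,
                 chi = chi, noise_amplitude = noise_amplitude,
                 oscillations = oscillations, coupling = coupling,
                 channel_labels = channel_labels, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic resting-state recording
#'
#' Each channel is the sum of independent `1/f^chi` background noise, the
#' weighted oscillations of the spec, and -- for coupled pairs -- a shared
#' latent colored component injected into channel `i` directly and into
#' channel `j` with the stated sample delay, both at `strength` standard
#' deviations relative to the background.
#'
#' @param spec a [synthetic_spec()].
#' @param state_label,subject_id metadata for the resulting recording.
#' @return An [eeg_recording()].
#' @export
sim_recording <- function(spec, state_label = "synthetic", subject_id = "s01") {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- round(spec$duration_s * spec$fs)
  nc <- spec$n_channels
  local_seed(spec$seed, {
    x <- matrix(0, nc, n)
    for (ch in seq_len(nc))
      x[ch, ] <- spec$noise_amplitude *
        sim_colored_noise(spec$chi, n, spec$fs)
    # each channel gets its own realization of the oscillation (same
    # spectral content, independent phase) so connectivity reflects only
    # the explicit coupling structure, not a shared waveform
    for (osc in spec$oscillations) {
      w <- rep_len(osc$weights, nc)
      for (ch in which(w != 0))
        x[ch, ] <- x[ch, ] + w[ch] *
          sim_oscillation(osc$center_freq, osc$bandwidth, osc$amplitude,
                          n, spec$fs)
    }
    if (!is.null(spec$coupling)) {
      for (r in seq_len(nrow(spec$coupling))) {
        cp <- spec$coupling[r, ]
        # the shared latent is broadband (mildly colored) regardless of the
        # background exponent, so coupling stays detectable by symbolic
        # measures even under steep 1/f backgrounds
        z_chi <- if (!is.null(spec$coupling$latent_chi)) cp$latent_chi else 0.5
        z <- sim_colored_noise(z_chi, n + cp$delay, spec$fs)
        x[cp$i, ] <- x[cp$i, ] + cp$strength * z[seq_len(n) + cp$delay]
        x[cp$j, ] <- x[cp$j, ] + cp$strength * z[seq_len(n)]
      }
    }
    eeg_recording(x, fs = spec$fs, channel_labels = spec$channel_labels,
                  state_label = state_label, subject_id = subject_id)
  })
}

#' Synthetic template-switching microstate EEG
#'
#' Piecewise-constant activation of `k` scalp templates: run lengths are
#' geometric with the requested mean (memoryless switching; a fixed-length
#' option supports exact-arithmetic tests), the next template is drawn from
#' a transition matrix (default: uniform over the other templates), each
#' segment carries a random polarity, and within a segment the template is
#' modulated by a sinusoidal activation so global field power oscillates.
#' White noise is added at the requested signal-to-noise ratio (RMS ratio).
#'
#' @param templates k x channels matrix of template maps (average-referenced
#'   and unit-normalized internally).
#' @param mean_duration_s mean dwell time per segment (s), `> 2/fs`.
#' @param fs,duration_s sampling rate and total duration.
#' @param snr RMS signal-to-noise ratio; `Inf` for noiseless.
#' @param seed integer seed.
#' @param transition optional k x k transition matrix (rows summing to 1,
#'   zero diagonal).
#' @param activation_freq modulation frequency (Hz) of the within-segment
#'   activation envelope.
#' @param fixed_length if `TRUE`, every run has exactly
#'   `round(mean_duration_s * fs)` samples.
#' @param channel_labels montage labels for the recording.
#' @return A list with `recording` (an [eeg_recording()]) and `labels`
#'   (integer ground-truth template index per sample, 1-based).
#' @export
sim_microstate_eeg <- function(templates, mean_duration_s, fs, duration_s,
                               snr = 5, seed = NULL, transition = NULL,
                               activation_freq = 11, fixed_length = FALSE,
                               channel_labels = NULL) {
  templates <- as.matrix(templates)
  k <- nrow(templates)
  if (k < 2) stop("need at least 2 templates")
  if (any(mean_duration_s <= 2 / fs)) stop("`mean_duration_s` must exceed 2/fs")
  templates <- normalize_maps(templates)
  if (any(!is.finite(templates)))
    stop("degenerate (constant) template map")
  gram <- tcrossprod(templates)
  if (any(abs(gram[upper.tri(gram)]) > 1 - 1e-10))
    stop("degenerate (identical up to sign) templates")
  if (!is.null(transition)) {
    if (any(abs(rowSums(transition) - 1) > 1e-9))
      stop("transition matrix rows must sum to 1")
  }
  n <- round(duration_s * fs)
  mean_len <- if (length(mean_duration_s) == 1L)
    rep(mean_duration_s * fs, k) else mean_duration_s * fs
  local_seed(seed, {
    labels <- integer(n)
    state <- sample.int(k, 1)
    pos <- 1L
    x <- matrix(0, ncol(templates), n)
    tt <- seq_len(n) / fs
    while (pos <= n) {
      len <- if (fixed_length) round(mean_len[state])
             else rgeom(1, 1 / mean_len[state]) + 1L
      idx <- pos:min(pos + len - 1L, n)
      labels[idx] <- state
      pol <- sample(c(-1, 1), 1)
      phase <- runif(1, 0, 2 * pi)
      # envelope stays away from zero so no sample is noise-only
      act <- 0.65 + 0.35 * sin(2 * pi * activation_freq * tt[idx] + phase)
      x[, idx] <- pol * outer(templates[state, ], act)
      pos <- pos + len
      state <- if (is.null(transition)) {
        others <- setdiff(seq_len(k), state)
        if (length(others) == 1L) others else sample(others, 1)
      } else {
        sample.int(k, 1, prob = transition[state, ])
      }
    }
    if (is.finite(snr)) {
      noise_sd <- sqrt(mean(x^2)) / snr
      x <- x + matrix(rnorm(length(x), sd = noise_sd), nrow(x))
    }
    if (is.null(channel_labels))
      channel_labels <- if (ncol(templates) == 19) standard_1020()
                        else paste0("ch", seq_len(ncol(templates)))
    list(recording = eeg_recording(x, fs = fs, channel_labels = channel_labels,
                                   state_label = "synthetic_microstate"),
         labels = labels)
  })
}

#' Synthetic low-rank TMS-evoked epochs
#'
#' The trial-averaged evoked response is a sum of `latent_rank` orthonormal
#' spatial modes, each driven by a smooth Gaussian-windowed oscillatory time
#' course confined to the post-stimulus window; trials add i.i.d. Gaussian
#' noise at the requested RMS signal-to-noise ratio. The generating rank is
#' recorded in attribute `"latent_rank"`.
#'
#' @param n_trials,n_channels,n_samples array dimensions.
#' @param latent_rank number of spatial modes, `1 <= latent_rank <=
#'   n_channels`.
#' @param snr RMS signal-to-noise ratio of single trials; `Inf` noiseless.
#' @param seed integer seed.
#' @param fs sampling rate (Hz).
#' @param onset_index 0-based stimulus onset sample.
#' @return An [eeg_epochs()] with attribute `latent_rank`.
#' @export
sim_evoked_epochs <- function(n_trials, n_channels, n_samples, latent_rank,
                              snr = 3, seed = NULL, fs = 1000,
                              onset_index = round(n_samples / 5)) {
  if (latent_rank < 1 || latent_rank > n_channels)
    stop("`latent_rank` must lie in [1, n_channels]")
  local_seed(seed, {
    modes <- qr.Q(qr(matrix(rnorm(n_channels * latent_rank), n_channels)))
    t_post <- (seq_len(n_samples) - 1 - onset_index) / fs
    courses <- matrix(0, latent_rank, n_samples)
    for (r in seq_len(latent_rank)) {
      f_r <- 4 + 3 * r
      center <- 0.05 + 0.2 * (r - 1) / max(1, latent_rank - 1)
      env <- exp(-((t_post - center) / 0.08)^2)
      env[t_post < 0] <- 0
      courses[r, ] <- sin(2 * pi * f_r * t_post) * env
    }
    evoked <- modes %*% courses
    arr <- array(0, c(n_trials, n_channels, n_samples))
    noise_sd <- if (is.finite(snr)) sqrt(mean(evoked^2)) / snr else 0
    for (tr in seq_len(n_trials))
      arr[tr, , ] <- evoked +
        matrix(rnorm(n_channels * n_samples, sd = noise_sd), n_channels)
    ep <- eeg_epochs(arr, fs = fs, onset_index = onset_index)
    attr(ep, "latent_rank") <- latent_rank
    ep
  })
}

#' State presets for synthetic cohorts
#'
#' Named parameter bundles encoding, as generator deltas, the directional
#' group differences the feature pipelines are expected to detect. Relative
#' to `"nor"` (healthy-control-like), `"uws"` has a steeper aperiodic
#' exponent and longer intrinsic timescale, raised delta and suppressed
#' posterior alpha, weaker and less integrated coupling (a sparse chain
#' rather than a ring-plus-shortcuts topology), a longer microstate-A dwell
#' time, and a lower-rank evoked response; `"mcs"` sits in between.
#'
#' @param name one of `"nor"`, `"mcs"`, `"uws"`.
#' @return A list of generator parameters consumed by [sim_cohort()].
#' @export
state_preset <- function(name = c("nor", "mcs", "uws")) {
  name <- match.arg(name)
  post <- as.numeric(assign_regions(standard_1020()) == "parieto_occipital")
  front <- as.numeric(assign_regions(standard_1020()) == "frontal")
  # small-world coupling: ring plus triangle-closing chords plus long-range
  # shortcuts (26 edges, exactly the 15% proportional-threshold budget on 19
  # channels) -> high clustering, short paths
  smallworld <- function(strength, latent_chi = 0.5) {
    e <- rbind(cbind(1:19, c(2:19, 1)),                # ring
               cbind(c(1, 6, 11, 16), c(3, 8, 13, 18)), # chords
               cbind(c(2, 7, 12), c(11, 16, 4)))        # shortcuts
    data.frame(i = e[, 1], j = e[, 2],
               strength = strength * c(rep(1, 19), rep(1.06, 4), rep(1.18, 3)),
               delay = 2L, latent_chi = latent_chi)
  }
  # chain-plus-weak-chords: fragmented short-range coupling with no
  # triangle-closing edges (26 edges) -> low clustering, long paths
  chain <- function(strength, chord_strength, latent_chi = 1.0) {
    ci <- seq(1, 15, by = 2)
    data.frame(i = c(1:18, ci), j = c(2:19, ci + 3),
               strength = c(rep(strength, 18), rep(chord_strength, length(ci))),
               delay = 2L, latent_chi = latent_chi)
  }
  switch(name,
    nor = list(
      state = "NOR", chi = 1.0,
      oscillations = list(
        list(center_freq = 10, bandwidth = 1.5, amplitude = 1.6,
             weights = 0.5 + 1.2 * post),
        list(center_freq = 2.5, bandwidth = 1.0, amplitude = 0.7, weights = 1),
        list(center_freq = 38, bandwidth = 5, amplitude = 0.35, weights = 1)),
      coupling = smallworld(0.8),
      ms_duration_s = c(0.08, 0.08, 0.08, 0.08),
      evoked_rank = 6L),
    mcs = list(
      state = "MCS", chi = 1.4,
      oscillations = list(
        list(center_freq = 10, bandwidth = 1.5, amplitude = 1.0,
             weights = 0.5 + 0.8 * post),
        list(center_freq = 2.5, bandwidth = 1.0, amplitude = 1.2, weights = 1),
        list(center_freq = 38, bandwidth = 5, amplitude = 0.3, weights = 1)),
      coupling = smallworld(0.55, latent_chi = 0.8),
      ms_duration_s = c(0.095, 0.08, 0.08, 0.08),
      evoked_rank = 3L),
    uws = list(
      state = "UWS", chi = 1.8,
      oscillations = list(
        list(center_freq = 10, bandwidth = 1.5, amplitude = 0.5,
             weights = 0.5 + 0.4 * post + 0.2 * front),
        list(center_freq = 2.5, bandwidth = 1.0, amplitude = 1.8, weights = 1),
        list(center_freq = 38, bandwidth = 5, amplitude = 0.25, weights = 1)),
      coupling = chain(0.35, 0.3),
      ms_duration_s = c(0.12, 0.08, 0.08, 0.08),
      evoked_rank = 1L))
}

#' Cohort specification and generation
#'
#' Generates per-subject synthetic data for two or more state presets.
#' Subject-level multiplicative jitter (log-normal, 5% scale) perturbs the
#' aperiodic exponent, oscillation amplitudes, coupling strengths and
#' microstate dwell times around the preset means; in a paired design the
#' same subject-level jitter is reused across states so subjects are matched.
#'
#' @param presets named list of presets from [state_preset()] (or the same
#'   structure built by hand).
#' @param n_subjects subjects per state (>= 2).
#' @param paired logical; reuse subject identities and jitter across states.
#' @param seed integer seed.
#' @param duration_s,fs resting-recording duration and sampling rate.
#' @param components which per-subject data products to generate: any of
#'   `"rest"`, `"microstate"`, `"evoked"`.
#' @param jitter_sd log-scale standard deviation of subject jitter.
#' @return `cohort_spec` returns a specification list; `sim_cohort` returns
#'   a nested list `result[[state]][[subject]]` whose elements hold `rest`
#'   (an [eeg_recording()]), `microstate` (list of recording + true labels)
#'   and `evoked` (an [eeg_epochs()]) as requested.
#' @export
cohort_spec <- function(presets, n_subjects = 20, paired = FALSE, seed = 1L,
                        duration_s = 60, fs = 100,
                        components = c("rest", "microstate", "evoked"),
                        jitter_sd = 0.05) {
  if (n_subjects < 2) stop("need at least 2 subjects per state")
  if (is.null(names(presets)))
    names(presets) <- vapply(presets, `[[`, "", "state")
  structure(list(presets = presets, n_subjects = as.integer(n_subjects),
                 paired = paired, seed = as.integer(seed),
                 duration_s = duration_s, fs = fs, components = components,
                 jitter_sd = jitter_sd),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
sim_cohort <- function(presets, n_subjects = 20, paired = FALSE, seed = 1L,
                       duration_s = 60, fs = 100,
                       components = c("rest", "microstate", "evoked"),
                       jitter_sd = 0.05) {
  if (inherits(presets, "cohort_spec")) {
    cs <- presets
  } else {
    cs <- cohort_spec(presets, n_subjects, paired, seed, duration_s, fs,
                      components, jitter_sd)
  }
  canon <- canonical_microstate_maps()
  local_seed(cs$seed, {
    n_states <- length(cs$presets)
    # subject-level jitter factors; paired designs share them across states
    jit <- function() exp(rnorm(6, sd = cs$jitter_sd))
    subj_jit <- replicate(cs$n_subjects, jit(), simplify = FALSE)
    out <- list()
    for (s_idx in seq_along(cs$presets)) {
      p <- cs$presets[[s_idx]]
      st <- names(cs$presets)[s_idx]
      out[[st]] <- vector("list", cs$n_subjects)
      for (sub in seq_len(cs$n_subjects)) {
        jv <- if (cs$paired) subj_jit[[sub]] else jit()
        sid <- if (cs$paired) sprintf("sub%02d", sub)
               else sprintf("%s%02d", tolower(st), sub)
        osc <- lapply(p$oscillations, function(o) {
          o$amplitude <- o$amplitude * jv[2]; o
        })
        cp <- p$coupling
        if (!is.null(cp)) cp$strength <- pmin(1, cp$strength * jv[3])
        spec <- synthetic_spec(
          n_channels = 19, duration_s = cs$duration_s, fs = cs$fs,
          chi = p$chi * jv[1], oscillations = osc, coupling = cp,
          seed = sample.int(.Machine$integer.max, 1))
        entry <- list(state = st, subject_id = sid)
        if ("rest" %in% cs$components)
          entry$rest <- sim_recording(spec, state_label = st, subject_id = sid)
        if ("microstate" %in% cs$components) {
          ms <- sim_microstate_eeg(
            canon, mean_duration_s = p$ms_duration_s * jv[4],
            fs = 250, duration_s = cs$duration_s, snr = 5,
            seed = sample.int(.Machine$integer.max, 1))
          ms$recording$state_label <- st
          ms$recording$subject_id <- sid
          entry$microstate <- ms
        }
        if ("evoked" %in% cs$components)
          entry$evoked <- sim_evoked_epochs(
            n_trials = 20, n_channels = 32, n_samples = 500,
            latent_rank = p$evoked_rank, snr = 3,
            seed = sample.int(.Machine$integer.max, 1), fs = 1000,
            onset_index = 100)
        out[[st]][[sub]] <- entry
      }
    }
    out
  })
}
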