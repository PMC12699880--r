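test_that("colored noise is deterministic, zero-mean, and slope-correct", {
  x <- sim_colored_noise(1, 4096, 250, seed = 11)
  expect_identical(x, sim_colored_noise(1, 4096, 250, seed = 11))
  expect_lt(abs(mean(x)), 1e-10)
  expect_error(sim_colored_noise(-0.5, 1024, 250), "non-negative")

  # white noise: flat spectrum over 1-30 Hz
  w <- sim_colored_noise(0, 2^17, 250, seed = 5)
  est <- compute_psd(eeg_recording(matrix(w, 1), 250), 10)
  expect_lt(abs(fit_aperiodic(est)$exponent), 0.05)

  # chi = 2 recovered by the aperiodic fitter
  y <- sim_colored_noise(2, 2^17, 250, seed = 6)
  est2 <- compute_psd(eeg_recording(matrix(y, 1), 250), 10)
  expect_lt(abs(fit_aperiodic(est2)$exponent - 2), 0.1)
})

test_that("oscillations are narrowband with the requested centroid", {
  o <- sim_oscillation(10, 1, 2, 2^16, 250, seed = 3)
  est <- compute_psd(eeg_recording(matrix(o, 1), 250), 10)
  expect_lt(abs(center_frequency(est, c(1, 45))[[1]] - 10), 0.3)
  expect_gt(relative_band_power(est, c(9, 11), c(1, 45))[[1]], 0.9)
  # RMS matches a sinusoid of the requested peak amplitude
  expect_equal(sqrt(mean(o^2)), 2 / sqrt(2), tolerance = 1e-4)

  expect_equal(sim_oscillation(10, 1, 0, 100, 250), numeric(100))
  # bandwidth -> 0 degenerates to a pure sinusoid
  s <- sim_oscillation(10, 0, 1, 2500, 250, seed = 1)
  est_s <- compute_psd(eeg_recording(matrix(s, 1), 250), 10)
  pk <- est_s$freqs[which.max(est_s$psd[1, ])]
  expect_equal(pk, 10)
  expect_error(sim_oscillation(200, 1, 1, 100, 250), "fs/2")
})

test_that("synthetic recordings honor shape, topography and coupling", {
  spec <- synthetic_spec(n_channels = 19, duration_s = 10, fs = 250, seed = 2)
  rec <- sim_recording(spec)
  expect_equal(dim(rec$data), c(19L, 2500L))
  expect_identical(sim_recording(spec)$data, rec$data) # same seed, same data

  # posterior-weighted alpha shows up as posterior-dominant relative power
  post <- as.numeric(assign_regions(standard_1020()) == "parieto_occipital")
  spec_a <- synthetic_spec(
    19, 40, 250, chi = 1,
    oscillations = list(list(center_freq = 10, bandwidth = 1.5,
                             amplitude = 2, weights = 0.3 + 1.5 * post)),
    seed = 8)
  rp <- relative_band_power(compute_psd(sim_recording(spec_a), 10), c(8, 13))
  topo <- band_topography(rp, assign_regions(standard_1020()))
  expect_gt(topo[["parieto_occipital"]], topo[["frontal"]])

  # zero coupling leaves PCMI at chance level
  spec0 <- synthetic_spec(2, 60, 100, chi = 0.5,
                          coupling = data.frame(i = 1, j = 2, strength = 0,
                                                delay = 2),
                          seed = 4)
  rec0 <- sim_recording(spec0)
  expect_lt(as.numeric(pcmi_pair(rec0$data[1, ], rec0$data[2, ])), 0.01)
})

test_that("microstate generator produces geometric runs recoverable by backfit", {
  tm <- canonical_microstate_maps()
  ms <- sim_microstate_eeg(tm, mean_duration_s = 0.08, fs = 250,
                           duration_s = 60, snr = 5, seed = 9)
  runs <- rle(ms$labels)$lengths
  expect_lt(abs(mean(runs) / 250 - 0.08), 0.01)
  expect_identical(ms$labels,
                   sim_microstate_eeg(tm, 0.08, 250, 60, 5, seed = 9)$labels)

  # noiseless limit: backfitting the true templates recovers the labels
  msc <- sim_microstate_eeg(tm, 0.08, 250, 20, snr = Inf, seed = 10)
  lab <- backfit(msc$recording, tm)
  expect_gte(mean(lab == msc$labels), 0.99)

  # a deterministic 2-state transition matrix alternates strictly
  t2 <- tm[1:2, ]
  ms2 <- sim_microstate_eeg(t2, 0.08, 250, 5, snr = Inf, seed = 1,
                            transition = matrix(c(0, 1, 1, 0), 2))
  r2 <- rle(ms2$labels)$values
  expect_true(all(r2[-1] != r2[-length(r2)]))
  expect_error(sim_microstate_eeg(tm[c(1, 1), ], 0.08, 250, 5), "degenerate")
})

test_that("evoked generator realizes the requested latent rank", {
  ep <- sim_evoked_epochs(10, 16, 400, latent_rank = 1, snr = Inf, seed = 3,
                          onset_index = 100)
  expect_identical(ep$data,
                   sim_evoked_epochs(10, 16, 400, 1, Inf, seed = 3,
                                     onset_index = 100)$data)
  dec <- pca_window(average_evoked(ep), window = c(0, 0.3))
  expect_equal(dec$eigenvalues[1], 16, tolerance = 1e-6)
  expect_lt(max(dec$eigenvalues[-1]), 1e-6)
  expect_error(sim_evoked_epochs(10, 16, 400, 17, 3), "latent_rank")

  # richer latent structure yields higher effective dimensionality
  mean_ed <- function(k) mean(vapply(1:8, function(s) {
    e <- sim_evoked_epochs(15, 32, 500, k, snr = 3, seed = s)
    effective_dimensionality(pca_window(average_evoked(e)))$ed
  }, numeric(1)))
  expect_gt(mean_ed(5), mean_ed(1))
})

test_that("cohorts respect design structure and recover preset contrasts", {
  coh <- sim_cohort(list(A = state_preset("nor"), B = state_preset("uws")),
                    n_subjects = 2, seed = 3, duration_s = 15, fs = 100,
                    components = "rest")
  expect_length(coh$A, 2L)
  expect_length(coh$B, 2L)
  expect_false(coh$A[[1]]$subject_id == coh$B[[1]]$subject_id)

  paired <- sim_cohort(list(A = state_preset("nor"), B = state_preset("uws")),
                       n_subjects = 2, paired = TRUE, seed = 3,
                       duration_s = 15, fs = 100, components = "rest")
  expect_identical(paired$A[[1]]$subject_id, paired$B[[1]]$subject_id)

  # injected aperiodic-exponent contrast is recovered in the right direction
  chi_hat <- function(entries) mean(vapply(entries, function(e) {
    mean(fit_aperiodic(compute_psd(e$rest, 10))$exponent)
  }, numeric(1)))
  coh2 <- sim_cohort(list(NOR = state_preset("nor"),
                          UWS = state_preset("uws")),
                     n_subjects = 4, seed = 5, duration_s = 30, fs = 100,
                     components = "rest")
  expect_gt(chi_hat(coh2$UWS), chi_hat(coh2$NOR))
})
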