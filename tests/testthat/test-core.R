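test_that("recording construction validates shape, labels and finiteness", {
  rec <- eeg_recording(matrix(rnorm(2000), 2), fs = 100)
  expect_equal(duration(rec), 10)
  expect_equal(rec$channel_labels, c("ch1", "ch2"))

  expect_error(eeg_recording(matrix(1:6, 2), fs = 100,
                             channel_labels = c("a", "b", "c")),
               "shape mismatch")
  expect_error(eeg_recording(matrix(c(1, NA, 3, 4), 2), fs = 100),
               "non-finite")
  expect_error(eeg_recording(matrix(1:4, 2), fs = -1), "fs")
})

test_that("epochs validate onset bounds and label count", {
  arr <- array(rnorm(30 * 64 * 500), c(30, 64, 500))
  ep <- eeg_epochs(arr, fs = 1000, onset_index = 100)
  expect_equal(dim(ep$data)[3] - ep$onset_index, 400) # post-stimulus span
  expect_error(eeg_epochs(arr, fs = 1000, onset_index = 500), "onset_index")
  expect_error(eeg_epochs(arr, fs = 1000, onset_index = 100,
                          channel_labels = c("a", "b")), "label count")
})

test_that("matrix + sidecar fixtures round-trip exactly", {
  rec <- eeg_recording(matrix(rnorm(500), 2), fs = 100,
                       channel_labels = c("Fp1", "O2"),
                       state_label = "awake", subject_id = "s07")
  path <- file.path(tempdir(), "rt_rec.tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$fs, 100)
  expect_equal(back$state_label, "awake")
  expect_equal(back$subject_id, "s07")

  ep <- eeg_epochs(array(rnorm(3 * 4 * 50), c(3, 4, 50)), fs = 250,
                   onset_index = 10)
  epath <- file.path(tempdir(), "rt_ep.tsv")
  write_epochs(ep, epath)
  back_ep <- read_epochs(epath)
  expect_equal(back_ep$data, ep$data, tolerance = 1e-12)
  expect_equal(back_ep$onset_index, 10L)

  expect_error(read_recording(file.path(tempdir(), "absent.tsv")),
               "sidecar")
})

test_that("EDF writer/reader round-trips within 16-bit quantization", {
  set.seed(4)
  x <- matrix(rnorm(2 * 500, sd = 40), 2) # +-~150 uV range
  rec <- eeg_recording(x, fs = 100, channel_labels = c("Cz", "Pz"),
                       state_label = "awake", subject_id = "edf01")
  path <- file.path(tempdir(), "rt.edf")
  write_edf(rec, path)
  back <- read_edf(path)
  rng <- apply(x, 1, function(r) diff(range(r)))
  qstep <- rng / 65535
  expect_lt(max(abs(back$data - x)), max(qstep))
  expect_equal(back$channel_labels, c("Cz", "Pz"))
  expect_equal(back$fs, 100)
  # read_recording dispatches on the .edf extension
  expect_s3_class(read_recording(path), "eeg_recording")
})

test_that("feature tables round-trip and preserve unicode labels", {
  rows <- data.frame(subject = "s1", state = "awake",
                     channel = "Cö3", feature = "relpow_alpha",
                     value = 0.25)
  path <- file.path(tempdir(), "ft.csv")
  write_feature_table(rows, path)
  expect_length(readLines(path), 2L)
  back <- read_feature_table(path)
  expect_equal(back$channel, "Cö3")
  expect_equal(back$value, 0.25)
  expect_error(write_feature_table(transform(rows, value = "x"), path),
               "numeric")
})

test_that("region assignment follows the 10-20 prefix rule", {
  expect_equal(as.character(assign_regions(c("Fp1", "Cz", "O2"))[1:3]),
               c("frontal", "central", "parieto_occipital"))
  expect_equal(as.character(assign_regions("X99")[1]), "other")
  expect_equal(as.character(assign_regions(c("FC1", "CP2", "AF3", "PO7", "TP9"))),
               c("central", "central", "frontal", "parieto_occipital",
                 "parieto_occipital"))
  counts <- table(assign_regions(standard_1020()))
  expect_equal(unname(counts[c("frontal", "central", "parieto_occipital")]),
               array(c(7L, 7L, 5L)))
  # total and deterministic
  expect_identical(assign_regions(standard_1020()),
                   assign_regions(standard_1020()))
})

test_that("recording validation flags flat channels and Nyquist violations", {
  clean <- eeg_recording(matrix(rnorm(400), 2), fs = 100)
  expect_equal(nrow(validate_recording(clean)), 0L)

  flat <- eeg_recording(rbind(rnorm(200), 0), fs = 100)
  rep_flat <- validate_recording(flat)
  expect_true("flat_channel" %in% rep_flat$check)

  slow <- eeg_recording(matrix(rnorm(400), 2), fs = 60)
  rep_slow <- validate_recording(slow) # gamma band to 45 Hz needs fs >= 90
  expect_true("nyquist" %in% rep_slow$check)
  expect_match(rep_slow$message[rep_slow$check == "nyquist"], "90")
})

test_that("configuration defaults match the analysis conventions", {
  cfg <- analysis_config()
  expect_equal(cfg$psd_window_s, 10)
  expect_equal(cfg$psd_overlap, 0)
  expect_equal(cfg$bands$delta, c(1, 4))
  expect_equal(cfg$bands$alpha, c(8, 13))
  expect_equal(cfg$bands$low_gamma, c(30, 45))
  expect_equal(cfg$aperiodic_fit_range, c(1, 30))
  expect_equal(cfg$acw_threshold, 0.5)
  expect_equal(cfg$display_density, 0.05)
  expect_equal(cfg$microstate_k, 4L)
  expect_equal(cfg$evoked_window, c(0, 0.3))
  expect_equal(cfg$fdr_q, 0.05)
  expect_error(analysis_config(bands = list(bad = c(5, 2))), "f_lo < f_hi")
  expect_error(analysis_config(graph_density = 1.5), "densities")

  path <- file.path(tempdir(), "cfg.json")
  write_config(cfg, path)
  expect_equal(read_config(path), cfg)
})
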