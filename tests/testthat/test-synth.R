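# Stage-conditioned generator: spectral structure, degenerate components,
# seeded determinism, hypnograms and cohort bookkeeping.

test_that("N3 epochs are delta-dominated in the periodogram", {
  prof <- dataset_profile("sleep_edf")
  ep <- generate_epoch("N3", prof, subject_params(), seed = 7)
  delta <- welch_bandpower(ep$eeg[1, ], prof$fs_eeg, c(0.5, 2))
  alpha <- welch_bandpower(ep$eeg[1, ], prof$fs_eeg, c(8, 12))
  expect_gt(delta, alpha)
})

test_that("each stage's signature band dominates its relative power increase", {
  prof <- dataset_profile("sleep_edf")
  sigs <- lapply(stage_profiles(), `[[`, "signature")
  for (stage in c("W", "N1", "N2", "N3", "REM")) {
    ok <- 0L
    n <- 40L
    for (i in seq_len(n)) {
      sj <- subject_params(noise_sd = 2)
      ep <- generate_epoch(stage, prof, sj, seed = 9000 + i)
      bg <- generate_epoch(stage, prof, sj, seed = 9000 + i,
                           components = c("background", "noise", "drift"))
      ratios <- vapply(names(sigs), function(s) {
        b <- sigs[[s]]$band
        if (sigs[[s]]$modality == "eeg") {
          welch_bandpower(ep$eeg[1, ], prof$fs_eeg, b) /
            welch_bandpower(bg$eeg[1, ], prof$fs_eeg, b)
        } else {
          welch_bandpower(ep$eog[1, ], prof$fs_eog, b) /
            welch_bandpower(bg$eog[1, ], prof$fs_eog, b)
        }
      }, 0)
      if (names(which.max(ratios)) == stage) ok <- ok + 1L
    }
    expect_gte(ok / n, 0.95)
  }
})

test_that("noise-free drift-only epochs equal the deterministic drift line", {
  prof <- dataset_profile("sleep_edf")
  sj <- subject_params(gain = 1.5, drift_slope = 0.2, drift_amp = 0,
                       noise_sd = 0)
  ep <- generate_epoch("N2", prof, sj, seed = 1, components = "drift",
                       t_offset = 60)
  t <- 60 + (seq_len(prof$samples_eeg) - 1) / prof$fs_eeg
  expect_equal(ep$eeg[1, ], 1.5 * drift_signal(sj, t), tolerance = 1e-12)
  expect_equal(ep$eeg[2, ], ep$eeg[1, ], tolerance = 1e-12)
})

test_that("epoch generation is bit-identical under a fixed seed", {
  prof <- dataset_profile("sleep_edf")
  a <- generate_epoch("W", prof, subject_params(), seed = 7)
  b <- generate_epoch("W", prof, subject_params(), seed = 7)
  expect_identical(a, b)
})

test_that("REM epochs carry opposite-polarity burst pairs on dual EOG", {
  prof <- dataset_profile("shhs")
  ep <- generate_epoch("REM", prof, subject_params(noise_sd = 0), seed = 3,
                       components = "events")
  expect_equal(ep$eog[2, ], -ep$eog[1, ], tolerance = 1e-12)
  expect_gt(max(abs(ep$eog[1, ])), 0)
})

test_that("hypnogram generator respects the transition matrix", {
  ident <- diag(5)
  expect_identical(generate_hypnogram(40, ident, seed = 1, start = "W"),
                   rep(0L, 40))
  unif <- matrix(0.2, 5, 5)
  h <- generate_hypnogram(50000, unif, seed = 2)
  freq <- tabulate(h + 1L, 5) / 50000
  expect_true(all(abs(freq - 0.2) < 0.01))
  expect_identical(generate_hypnogram(100, seed = 9),
                   generate_hypnogram(100, seed = 9))
  bad <- matrix(0.25, 5, 5)
  expect_error(generate_hypnogram(10, bad), "sum to 1")
  expect_true(all(abs(rowSums(default_transition_matrix()) - 1) < 1e-12))
})

test_that("cohorts have the right bookkeeping and are reproducible", {
  prof <- tiny_profile()
  ds <- generate_cohort(5, 40, prof, imbalance = rep(1, 5), master_seed = 1)
  expect_equal(n_epochs(ds), 200L)
  expect_equal(length(unique(ds$subject_ids)), 5L)
  expect_equal(dim(ds$eeg), c(200L, 2L, 960L))
  ds2 <- generate_cohort(5, 40, prof, imbalance = rep(1, 5), master_seed = 1)
  expect_identical(ds$eeg, ds2$eeg)
  expect_identical(ds$labels, ds2$labels)
})

test_that("subject gain shows up in the raw RMS ratio", {
  prof <- tiny_profile()
  subjects <- list(subject_params(gain = 1, drift_slope = 0, drift_amp = 0, id = 1),
                   subject_params(gain = 3, drift_slope = 0, drift_amp = 0, id = 2))
  ds <- generate_cohort(2, 30, prof, imbalance = rep(1, 5), master_seed = 2,
                        subjects = subjects)
  rms <- function(x) sqrt(mean(x^2))
  r1 <- rms(ds$eeg[ds$subject_ids == 1, , ])
  r2 <- rms(ds$eeg[ds$subject_ids == 2, , ])
  expect_equal(r2 / r1, 3, tolerance = 0.15)
})

test_that("stage profile validation rejects impossible bands", {
  prof <- dataset_profile("custom", eeg_channels = 1, eog_channels = 0,
                          fs_eeg = 10, fs_eog = 10)
  expect_error(generate_epoch("W", prof), "Nyquist")
  tweaked <- stage_profiles(tweaks = list(N3 = list(band_amp = 0.5)))
  expect_equal(tweaked$N3$bands[[1]][3], 30)
  expect_error(stage_profiles(tweaks = list(XX = list(band_amp = 1))), "unknown stage")
})
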