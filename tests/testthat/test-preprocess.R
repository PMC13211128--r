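# Detrending, z-scoring, segmentation, harmonization and the pipeline laws.

test_that("linear detrending removes exactly the least-squares line", {
  t <- seq_len(1000)
  expect_equal(detrend_linear(3.5 * t + 2), rep(0, 1000), tolerance = 1e-9)
  expect_equal(detrend_linear(numeric(1000)), numeric(1000))
  s <- sin(2 * pi * 50 * t / 1000)
  y <- s + 0.01 * t - 4
  out <- detrend_linear(y)
  # independent least-squares oracle via lm()
  expect_equal(out, unname(y - fitted(lm(y ~ t))), tolerance = 1e-9)
  expect_gt(cor(out, s), 0.999)            # oscillation preserved
  # the removed component is exactly a line
  resid <- y - out
  fit <- lm(resid ~ t)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_error(detrend_linear(1), "at least 2")
})

test_that("z-scoring normalizes per recording and flags degenerate channels", {
  set.seed(1)
  rec <- recording(eeg = rbind(rnorm(1e5, mean = 5, sd = 2)), fs_eeg = 100)
  z <- zscore_recording(rec)
  expect_equal(mean(z$eeg[1, ]), 0, tolerance = 1e-9)
  expect_equal(sd(z$eeg[1, ]), 1, tolerance = 1e-9)
  # idempotence on standardized input
  z2 <- zscore_recording(z)
  expect_equal(z2$eeg, z$eeg, tolerance = 1e-9)
  # constant channel -> zeros with a warning
  recc <- recording(eeg = rbind(rep(4, 100), rnorm(100)), fs_eeg = 10)
  expect_warning(zc <- zscore_recording(recc), "zero variance")
  expect_equal(zc$eeg[1, ], rep(0, 100))
})

test_that("segmentation arithmetic follows floor(total / (fs * epoch_s))", {
  prof <- dataset_profile("sleep_edf")
  rec <- recording(eeg = matrix(rnorm(2 * 100 * 61), 2),
                   eog = matrix(rnorm(1 * 100 * 61), 1), fs_eeg = 100)
  ds <- segment_epochs(rec, 30, profile = prof)
  expect_equal(n_epochs(ds), 2L)                       # 61 s -> 2 epochs
  expect_equal(dim(ds$eeg)[3], 3000L)                  # 100 Hz x 30 s
  rec200 <- recording(eeg = matrix(rnorm(200 * 60), 1), fs_eeg = 200)
  expect_equal(dim(segment_epochs(rec200, 30)$eeg)[3], 6000L)
  # epochs tile the recording from sample zero
  expect_equal(ds$eeg[2, 1, ], rec$eeg[1, 3001:6000])
  short <- recording(eeg = matrix(rnorm(100), 1), fs_eeg = 100)
  expect_warning(empty <- segment_epochs(short, 30), "shorter")
  expect_equal(n_epochs(empty), 0L)
})

test_that("polyphase resampling preserves lengths, tones and identity", {
  # SHHS EOG 50 -> 125 Hz: 1500 -> 3750 samples
  x <- rnorm(1500)
  y <- resample_poly(x, 5, 2)
  expect_length(y, 3750L)
  # pass-through at equal rates is bit-identical
  expect_identical(resample_poly(x, 3, 3), x)
  # bandlimited tone: correlation with the analytic resample > 0.999 and
  # energy preserved within 1%
  t50 <- (0:1499) / 50
  t125 <- (0:3749) / 125
  tone <- sin(2 * pi * 10 * t50)
  up <- resample_poly(tone, 5, 2)
  ref <- sin(2 * pi * 10 * t125)
  expect_gt(cor(up, ref), 0.999)
  expect_lt(abs(sum(up^2) / sum(ref^2) - 1), 0.01)
})

test_that("harmonization equalizes modality lengths on mixed-rate profiles", {
  prof <- dataset_profile("shhs")
  ds <- generate_cohort(1, 6, prof, imbalance = rep(1, 5), master_seed = 3)
  expect_equal(dim(ds$eeg)[3], 3750L)
  expect_equal(dim(ds$eog)[3], 1500L)
  h <- harmonize_rates(ds)
  expect_equal(h$fs_eog, 125)
  expect_equal(dim(h$eog)[3], 3750L)
  expect_identical(h$eeg, ds$eeg)   # already at target: untouched
  expect_match(tail(h$preprocessing_flags, 1), "harmonize")
  expect_error(harmonize_rates(ds, target_fs = 50), "allow_downsample")
})

test_that("the pipeline applies the stated steps in order and is idempotent", {
  prof <- tiny_profile()
  gen <- generate_subject_recording(prof, subject_params(gain = 2, drift_slope = 0.05,
                                                         drift_amp = 10),
                                    labels = rep(0:4, 4), seed = 11)
  rec1 <- preprocess_recording(gen$recording)
  expect_identical(rec1$preprocessing_flags, c("detrend", "zscore"))
  ds <- segment_epochs(rec1, profile = prof)
  expect_identical(ds$preprocessing_flags, c("detrend", "zscore", "segment"))
  # no other step ever appears
  expect_true(all(ds$preprocessing_flags %in% c("detrend", "zscore", "segment")))
  rec2 <- preprocess_recording(rec1)
  expect_equal(rec2$eeg, rec1$eeg, tolerance = 1e-6)
})
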