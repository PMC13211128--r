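# Shared fixtures. Training-scale tests run on a reduced-rate custom profile
# (32 Hz, 960 samples per 30-s epoch) so the whole suite fits a single-CPU
# budget; shape and arithmetic tests use the full-rate presets.

tiny_profile <- function() {
  dataset_profile("custom", eeg_channels = 2, eog_channels = 1,
                  fs_eeg = 32, fs_eog = 32)
}

tiny_config <- function(...) {
  model_config(eeg_channels = 2, eog_channels = 1, width_multiplier = 1 / 16, ...)
}

# memoized small preprocessed cohort shared across test files
.fixture_env <- new.env()

tiny_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(
      2, 100, tiny_profile(), imbalance = rep(1, 5),
      master_seed = 5, preprocess = TRUE)
  }
  .fixture_env$cohort
}

# a tiny trained model on the shared cohort (used by analysis tests)
tiny_trained <- function() {
  if (is.null(.fixture_env$trained)) {
    ds <- tiny_cohort()
    net <- build_model(tiny_config(), seed = 1)
    tc <- train_config(lr = 1e-3, weight_decay = 1e-4, epochs = 6,
                       batch_size = 32, val_fraction = 0.1, seed = 1)
    train_model(net, ds, config = tc)
    .fixture_env$trained <- net
  }
  .fixture_env$trained
}

rand_map <- function(C, Tt, B, seed = 1) {
  set.seed(seed)
  array(rnorm(C * Tt * B), c(C, Tt, B))
}

welch_bandpower <- function(x, fs, band) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0, detrend = TRUE)
  sum(sp$spec[sp$freq >= band[1] & sp$freq <= band[2]])
}
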