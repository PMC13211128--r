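# Correlation statistics, omnibus test and Grad-CAM contracts.

test_that("spearman rho equals the rank-Pearson oracle and is monotone-invariant", {
  set.seed(40)
  for (rep in 1:5) {
    x <- rnorm(20)
    y <- rnorm(20) + 0.5 * x
    expect_equal(spearman_epoch(x, y),
                 suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
  # ties handled by average ranks
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7)
  expect_equal(spearman_epoch(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  z <- rnorm(50)
  expect_equal(spearman_epoch(z, z^3), 1)            # strictly monotone map
  expect_equal(spearman_epoch(z, -z), -1)
  expect_equal(spearman_epoch(z, exp(2 * z)), spearman_epoch(z, z))
  expect_true(is.na(spearman_epoch(rep(1, 10), rnorm(10))))
  expect_error(spearman_epoch(1:3, 1:4), "length")
})

test_that("kruskal-wallis matches stats::kruskal.test including ties", {
  g1 <- list(c(1, 2, 3), c(10, 11, 12))
  kw <- kruskal_wallis(g1)
  ref <- kruskal.test(unlist(g1), factor(rep(1:2, each = 3)))
  expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(kw$p, ref$p.value, tolerance = 1e-12)
  set.seed(41)
  g2 <- list(round(rnorm(12), 1), round(rnorm(15), 1), round(rnorm(9), 1))
  kw2 <- kruskal_wallis(g2)
  ref2 <- kruskal.test(unlist(g2), factor(rep(1:3, times = lengths(g2))))
  expect_equal(kw2$H, unname(ref2$statistic), tolerance = 1e-12)
  # identical values across groups -> H = 0, p = 1
  expect_equal(kruskal_wallis(list(rep(2, 5), rep(2, 7)))$H, 0)
  expect_equal(kruskal_wallis(list(rep(2, 5), rep(2, 7)))$p, 1)
  expect_error(kruskal_wallis(list(1:3)), "two non-empty")
})

test_that("stage-wise correlation finds the planted N3 common component", {
  # the generator leaks N3 slow waves into the EOG; nothing else is shared
  prof <- tiny_profile()
  ds <- generate_cohort(2, 120, prof, imbalance = rep(1, 5), master_seed = 21,
                        preprocess = TRUE)
  res <- stagewise_correlation(ds)
  expect_true(all(names(res$medians_abs) == c("W", "N1", "N2", "N3", "REM")))
  expect_identical(names(which.max(res$medians_abs)), "N3")
  expect_lt(res$p, 1e-6)
  # deterministic given the dataset
  res2 <- stagewise_correlation(ds)
  expect_identical(res$medians, res2$medians)
})

test_that("independent white-noise modalities give near-zero medians", {
  set.seed(42)
  n <- 500L
  prof <- dataset_profile("custom", eeg_channels = 1, eog_channels = 1,
                          fs_eeg = 20, fs_eog = 20)
  ds <- epoch_dataset(eeg = array(rnorm(n * 600), c(n, 1, 600)),
                      eog = array(rnorm(n * 600), c(n, 1, 600)),
                      labels = rep(0:4, each = 100),
                      subject_ids = rep(1L, n), profile = prof)
  res <- stagewise_correlation(ds)
  expect_true(all(abs(res$medians) < 0.05))
})

test_that("grad-cam maps satisfy the shape and nonnegativity contracts", {
  net <- build_model(tiny_config(), seed = 50)   # frozen random weights
  prof <- tiny_profile()
  ep <- generate_epoch("N2", prof, subject_params(), seed = 60)
  for (tap in c("eeg_branch", "eog_branch", "gated_output")) {
    gm <- gradcam(net, ep$eeg, ep$eog, tap = tap, target_class = "N2")
    expect_length(gm$values, temporal_length(960L))
    expect_length(gm$upsampled, 960L)
    expect_true(all(gm$values >= 0))
    if (!gm$flagged_zero) expect_equal(max(gm$values), 1)
  }
})

test_that("grad-cam localizes planted spindle bursts after training", {
  # train a tiny model where the only N2-vs-N1 cue is the spindle burst,
  # then check the EEG-tap argmax lands inside a burst window
  prof <- tiny_profile()
  profs <- stage_profiles()
  profs$N2$bands <- profs$N1$bands      # identical background: burst is the cue
  ds <- generate_cohort(2, 120, prof, imbalance = c(0, 1, 1, 0, 0),
                        master_seed = 33, preprocess = TRUE, profiles = profs)
  net <- build_model(tiny_config(), seed = 51)
  tc <- train_config(lr = 1e-3, weight_decay = 1e-4, epochs = 12,
                     batch_size = 16, val_fraction = 0.1, seed = 3)
  train_model(net, ds, config = tc)
  hits <- 0L
  n_trials <- 20L
  L <- prof$samples_eeg
  stride <- as.integer(prof$fs_eeg)   # one feature stride = 1 s at L/32
  for (i in seq_len(n_trials)) {
    seed <- 7000 + i
    sj <- subject_params(noise_sd = 1)
    ep_full <- generate_epoch("N2", prof, sj, seed = seed, profiles = profs)
    ep_bg <- generate_epoch("N2", prof, sj, seed = seed, profiles = profs,
                            components = c("background", "oscillations",
                                           "noise", "drift"))
    # event support, dilated by one feature stride: stage-4 features carry a
    # 32-sample stride, so saliency localizes to that resolution at best
    burst <- abs(ep_full$eeg[1, ] - ep_bg$eeg[1, ]) > 1e-9
    dil <- rep(FALSE, L)
    for (b in which(burst)) {
      dil[max(1L, b - stride):min(L, b + stride)] <- TRUE
    }
    eeg <- ep_full$eeg
    eog <- ep_full$eog
    for (ch in 1:2) eeg[ch, ] <- (eeg[ch, ] - mean(eeg[ch, ])) / sd(eeg[ch, ])
    eog[1, ] <- (eog[1, ] - mean(eog[1, ])) / sd(eog[1, ])
    gm <- gradcam(net, eeg, eog, tap = "eeg_branch", target_class = "N2")
    if (dil[which.max(gm$upsampled)]) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.8)
})

test_that("branch probes show the cross-modal interaction benefit", {
  ds <- tiny_cohort()
  net <- tiny_trained()
  set.seed(77)
  test_idx <- sort(sample(n_epochs(ds), 50))
  train_idx <- setdiff(seq_len(n_epochs(ds)), test_idx)
  tc <- train_config(lr = 1e-3, weight_decay = 1e-4, epochs = 8,
                     batch_size = 16, val_fraction = 0, seed = 2)
  pr <- branch_probe(net, ds, mode = c("before", "after"), train_idx, test_idx,
                     tc, config_args = list(eeg_channels = 2, eog_channels = 1,
                                            width_multiplier = 1 / 16))
  expect_equal(nrow(pr), 4L)
  for (br in c("EEG", "EOG")) {
    before <- pr$OA[pr$branch == br & pr$mode == "before"]
    after <- pr$OA[pr$branch == br & pr$mode == "after"]
    expect_gte(after, before)   # interaction helps each branch
  }
  # a probe trained on shuffled labels scores near 5-class chance
  Xtr <- t(branch_features(net, ds, train_idx, "fbar_eeg"))
  Xte <- t(branch_features(net, ds, test_idx, "fbar_eeg"))
  set.seed(3)
  p <- probe_train(Xtr, sample(ds$labels[train_idx]))
  oa <- 100 * mean(p$predict(Xte) == ds$labels[test_idx])
  expect_lt(oa, 40)
  # deterministic given fixed seeds
  pr2 <- branch_probe(net, ds, mode = "after", train_idx, test_idx, tc)
  expect_identical(pr$OA[pr$mode == "after"], pr2$OA)
})
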