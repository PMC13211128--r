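# Architecture arithmetic, attention/fusion contracts and forward/backward
# behavior on tiny configurations.

# independent stride-arithmetic oracle: walk the layer schedule explicitly
oracle_temporal_length <- function(L) {
  out_len <- function(L, k, s, p) as.integer(floor((L + 2 * p - k) / s) + 1)
  t <- out_len(L, 7, 2, 3)   # stem conv
  t <- out_len(t, 3, 2, 1)   # stem max-pool
  t <- out_len(t, 3, 2, 1)   # stage 2 entry
  t <- out_len(t, 3, 2, 1)   # stage 3 entry
  out_len(t, 3, 2, 1)        # stage 4 entry
}

test_that("temporal length matches the layer-by-layer oracle", {
  for (L in c(3000L, 3200L, 3750L, 961L, 1000L, 1920L, 6000L, 33L)) {
    expect_identical(temporal_length(L), oracle_temporal_length(L))
  }
  expect_identical(temporal_length(3200L), 100L)  # L/32 exactly when 32 | L
  expect_identical(temporal_length(3000L), 94L)
  expect_identical(temporal_length(3750L), 118L)
  expect_error(temporal_length(16L), "minimum")
})

test_that("ECA adaptive kernel rule reproduces the configured sizes", {
  expect_identical(eca_kernel_size(2048), 7L)
  expect_identical(eca_kernel_size(128), 5L)
  expect_identical(eca_kernel_size(2), 1L)
  # config validator applies the rule to the fused width
  expect_identical(tiny_config()$eca_kernel, eca_kernel_size(2L * tiny_config()$embed_dim))
  expect_error(model_config(eca_kernel = 4), "odd")
})

test_that("backbone shapes follow the stride schedule on a tiny config", {
  cfg <- tiny_config()
  net <- build_model(cfg, seed = 2)
  L <- 960L; B <- 2L
  eeg <- rand_map(2, L, B, seed = 1)
  eog <- rand_map(1, L, B, seed = 2)
  out <- model_forward(net, eeg, eog, keep_intermediates = TRUE)
  Tt <- temporal_length(L)
  it <- out$intermediates
  expect_equal(dim(it$f_eeg), c(cfg$embed_dim, Tt, B))
  expect_equal(dim(it$f_eog), c(cfg$embed_dim, Tt, B))
  expect_equal(dim(it$f_fused), c(2L * cfg$embed_dim, Tt, B))
  expect_equal(dim(it$F), c(cfg$fused_dim, Tt, B))
  # per-stage widths and times (both branches share the stride schedule)
  pool_T <- floor((floor((L + 6 - 7) / 2) + 1 + 2 - 3) / 2) + 1
  times <- c(pool_T, floor((pool_T - 1) / 2) + 1)
  times <- c(times, floor((times[2] - 1) / 2) + 1)
  times <- c(times, floor((times[3] - 1) / 2) + 1)
  for (s in 1:4) {
    eeg_last <- it[[sprintf("eeg.s%d.b%d", s, cfg$eeg_block_counts[s])]]
    eog_last <- it[[sprintf("eog.s%d.b%d", s, cfg$eog_block_counts[s])]]
    expect_equal(dim(eeg_last), c(cfg$eeg_stage_widths[s], times[s], B))
    expect_equal(dim(eog_last), c(cfg$eog_stage_widths[s], times[s], B))
  }
  expect_equal(dim(out$logits), c(5L, B))
  expect_equal(colSums(out$probs), rep(1, B), tolerance = 1e-6)
  # channel mismatch is a shape error
  expect_error(model_forward(net, eog, eog), "channels")
})

test_that("zero-logit fusion pathways give exactly 0.5 * concat", {
  cfg <- tiny_config()
  net <- build_model(cfg, seed = 4)
  for (nm in grep("^fus\\.", names(net$params), value = TRUE)) {
    net$params[[nm]] <- net$params[[nm]] * 0
  }
  L <- 96L
  eeg <- rand_map(2, L, 2, seed = 3)
  eog <- rand_map(1, L, 2, seed = 4)
  out <- model_forward(net, eeg, eog, keep_intermediates = TRUE, use_gtca = FALSE)
  it <- out$intermediates
  expect_true(all(it$w_eog2eeg == 0.5) && all(it$w_eeg2eog == 0.5))
  C <- cfg$embed_dim
  expect_equal(it$f_fused[seq_len(C), , ], 0.5 * it$f_eeg[, , ], tolerance = 1e-12)
  expect_equal(it$f_fused[C + seq_len(C), , ], 0.5 * it$f_eog[, , ], tolerance = 1e-12)
})

test_that("all attention weights live strictly inside (0, 1)", {
  # batch statistics: an untrained net in eval mode has uncalibrated running
  # moments, so activations (and hence sigmoid logits) are unrepresentative
  net <- build_model(tiny_config(), seed = 5)
  out <- model_forward(net, rand_map(2, 96, 3, 1), rand_map(1, 96, 3, 2),
                       train = TRUE, keep_intermediates = TRUE)
  it <- out$intermediates
  for (w in list(it$w_eog2eeg, it$w_eeg2eog, it$a, it$g, it$eca_w)) {
    expect_true(all(w > 0 & w < 1))
  }
})

test_that("gate limits recover the two mixing extremes exactly", {
  cfg <- tiny_config()
  L <- 96L
  eeg <- rand_map(2, L, 2, seed = 6)
  eog <- rand_map(1, L, 2, seed = 7)
  for (bias in c(50, -50)) {
    net <- build_model(cfg, seed = 6)
    net$params[["gtca.gate.W"]] <- net$params[["gtca.gate.W"]] * 0
    net$params[["gtca.gate.b"]] <- rep(bias, cfg$fused_dim)
    out <- model_forward(net, eeg, eog, keep_intermediates = TRUE)
    it <- out$intermediates
    if (bias > 0) {
      expect_equal(it$f_gate, it$f_fused, tolerance = 1e-12)  # g == 1
    } else {
      expect_equal(it$f_gate, it$f_temp, tolerance = 1e-12)   # g == 0
    }
  }
})

test_that("constant pooled descriptor yields equal ECA weights across channels", {
  cfg <- tiny_config()
  net <- build_model(cfg, seed = 8)
  Cf <- cfg$fused_dim
  z <- array(1, c(1L, Cf, 2L))   # constant across the channel axis
  pad <- (cfg$eca_kernel - 1L) %/% 2L
  y <- conv1d_forward(z, net$params[["gtca.eca.W"]], NULL, 1L, pad)$out
  inner <- y[1, (pad + 1):(Cf - pad), ]  # away from the zero-padded rim
  expect_lt(max(apply(inner, 2, function(v) diff(range(v)))), 1e-12)
})

test_that("classification head is a softmax over five stages", {
  cfg <- tiny_config()
  net <- build_model(cfg, seed = 9)
  net$params[["head.fc.W"]] <- net$params[["head.fc.W"]] * 0
  net$params[["head.fc.b"]] <- numeric(5)
  out <- model_forward(net, rand_map(2, 96, 3, 1), rand_map(1, 96, 3, 2))
  expect_equal(out$probs, matrix(0.2, 5, 3), tolerance = 1e-12)
})

test_that("method-3 bypass equals the concatenation pipeline bit-exactly", {
  cfg5 <- tiny_config()
  net5 <- build_model(cfg5, seed = 10)
  eeg <- rand_map(2, 128, 2, seed = 8)
  eog <- rand_map(1, 128, 2, seed = 9)
  out_bypass <- model_forward(net5, eeg, eog, use_fusion = FALSE, use_gtca = FALSE)
  # independent method-3 net carrying the same shared weights
  cfg3 <- ablation_config(3, eeg_channels = 2, eog_channels = 1,
                          width_multiplier = 1 / 16)
  net3 <- build_model(cfg3, seed = 99)
  for (nm in names(net3$params)) net3$params[[nm]] <- net5$params[[nm]]
  net3$bn <- net5$bn[names(net3$bn)]
  out3 <- model_forward(net3, eeg, eog)
  expect_identical(out_bypass$logits, out3$logits)
})

test_that("eval-mode forward is deterministic and training is seeded", {
  net <- build_model(tiny_config(), seed = 11)
  eeg <- rand_map(2, 96, 2, seed = 10)
  eog <- rand_map(1, 96, 2, seed = 11)
  o1 <- model_forward(net, eeg, eog)
  o2 <- model_forward(net, eeg, eog)
  expect_identical(o1$logits, o2$logits)
  # same seed -> bit-identical initialization
  net2 <- build_model(tiny_config(), seed = 11)
  expect_identical(net$params, net2$params)
})

test_that("every parameter array receives gradient on a random batch", {
  net <- build_model(tiny_config(), seed = 12)
  eeg <- rand_map(2, 96, 8, seed = 12)
  eog <- rand_map(1, 96, 8, seed = 13)
  out <- model_forward(net, eeg, eog, train = TRUE)
  ce <- cross_entropy(out$logits, rep(0:4, length.out = 8))
  model_backward(net, out$ctx, ce$dlogits)
  for (nm in names(net$params)) {
    g <- net$grads[[nm]]
    expect_false(is.null(g), info = nm)
    expect_gt(max(abs(g)), 0, label = paste("grad of", nm))
  }
})

test_that("checkpoint round-trips and config serializes", {
  net <- build_model(tiny_config(), seed = 13)
  ck <- model_checkpoint(net)
  net$params[["head.fc.b"]] <- net$params[["head.fc.b"]] + 1
  model_restore(net, ck)
  expect_identical(net$params[["head.fc.b"]], ck$params[["head.fc.b"]])
  tf <- tempfile(fileext = ".json")
  config_write(net$config, tf)
  cfg2 <- config_read(tf)
  expect_equal(cfg2$eeg_stage_widths, net$config$eeg_stage_widths)
  expect_equal(cfg2$eca_kernel, net$config$eca_kernel)
})
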