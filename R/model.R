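# The fusion network: modality-specific residual backbones over raw 30-s
# epochs, a bidirectional cross-channel fusion module, a gated
# temporal-channel attention block and a linear head. Forward and backward
# passes are written explicitly (static graph); every layer keeps its cache
# in a per-call context so training, Grad-CAM and branch probes share one
# code path.

# ---- parameter registration -------------------------------------------------
reg_conv <- function(net, name, c_out, c_in, k, bias = FALSE) {
  p <- init_conv(c_out, c_in, k, bias = bias)
  net$params[[paste0(name, ".W")]] <- p$W
  if (bias) net$params[[paste0(name, ".b")]] <- p$b
  invisible(NULL)
}

reg_bn <- function(net, name, C) {
  p <- init_bn(C)
  net$params[[paste0(name, ".gamma")]] <- p$gamma
  net$params[[paste0(name, ".beta")]] <- p$beta
  net$bn[[name]] <- list(mean = numeric(C), var = rep(1, C))
  invisible(NULL)
}

reg_linear <- function(net, name, n_out, n_in) {
  p <- init_linear(n_out, n_in)
  net$params[[paste0(name, ".W")]] <- p$W
  net$params[[paste0(name, ".b")]] <- p$b
  invisible(NULL)
}

# ---- layer wrappers over a forward context ---------------------------------
acc_grad <- function(net, nm, g) {
  cur <- net$grads[[nm]]
  net$grads[[nm]] <- if (is.null(cur)) g else cur + g
}

conv_f <- function(net, ctx, name, x, stride = 1L, pad = 0L) {
  r <- conv1d_forward(x, net$params[[paste0(name, ".W")]],
                      net$params[[paste0(name, ".b")]], stride, pad)
  ctx$cache[[name]] <- r$cache
  r$out
}

conv_b <- function(net, ctx, name, dy) {
  r <- conv1d_backward(dy, ctx$cache[[name]], net$params[[paste0(name, ".W")]])
  acc_grad(net, paste0(name, ".W"), r$dW)
  if (!is.null(r$db)) acc_grad(net, paste0(name, ".b"), r$db)
  r$dx
}

bn_f <- function(net, ctx, name, x) {
  st <- net$bn[[name]]
  r <- bn_forward(x, net$params[[paste0(name, ".gamma")]],
                  net$params[[paste0(name, ".beta")]],
                  st$mean, st$var, train = ctx$train)
  if (ctx$train) net$bn[[name]] <- list(mean = r$running_mean, var = r$running_var)
  ctx$cache[[name]] <- r$cache
  r$out
}

bn_b <- function(net, ctx, name, dy) {
  r <- bn_backward(dy, ctx$cache[[name]])
  acc_grad(net, paste0(name, ".gamma"), r$dgamma)
  acc_grad(net, paste0(name, ".beta"), r$dbeta)
  r$dx
}

# fused conv-side pattern: batch norm immediately followed by ReLU
bnrelu_f <- function(net, ctx, name, x) {
  st <- net$bn[[name]]
  r <- bnrelu_forward(x, net$params[[paste0(name, ".gamma")]],
                      net$params[[paste0(name, ".beta")]],
                      st$mean, st$var, train = ctx$train)
  if (ctx$train) net$bn[[name]] <- list(mean = r$running_mean, var = r$running_var)
  ctx$cache[[name]] <- r$cache
  r$out
}

bnrelu_b <- function(net, ctx, name, dy) {
  r <- bnrelu_backward(dy, ctx$cache[[name]])
  acc_grad(net, paste0(name, ".gamma"), r$dgamma)
  acc_grad(net, paste0(name, ".beta"), r$dbeta)
  r$dx
}

relu_f <- function(ctx, name, x) {
  r <- relu_forward(x)
  ctx$cache[[name]] <- r$cache
  r$out
}
relu_b <- function(ctx, name, dy) relu_backward(dy, ctx$cache[[name]])

sigm_f <- function(ctx, name, x) {
  r <- sigmoid_forward(x)
  ctx$cache[[name]] <- r$cache
  r$out
}
sigm_b <- function(ctx, name, dy) sigmoid_backward(dy, ctx$cache[[name]])

pool_f <- function(ctx, name, x, k = 3L, stride = 2L, pad = 1L) {
  r <- maxpool1d_forward(x, k, stride, pad)
  ctx$cache[[name]] <- r$cache
  r$out
}
pool_b <- function(ctx, name, dy) maxpool1d_backward(dy, ctx$cache[[name]])

gap_f <- function(ctx, name, x) {
  r <- gap_time_forward(x)
  ctx$cache[[name]] <- r$cache
  r$out
}
gap_b <- function(ctx, name, dy) gap_time_backward(dy, ctx$cache[[name]])

lin_f <- function(net, ctx, name, x) {
  r <- linear_forward(x, net$params[[paste0(name, ".W")]], net$params[[paste0(name, ".b")]])
  ctx$cache[[name]] <- r$cache
  r$out
}

lin_b <- function(net, ctx, name, dy) {
  r <- linear_backward(dy, ctx$cache[[name]], net$params[[paste0(name, ".W")]])
  acc_grad(net, paste0(name, ".W"), r$dW)
  acc_grad(net, paste0(name, ".b"), r$db)
  r$dx
}

# broadcast a per-channel (C, B) weight over time -> (C, T, B)
bc_time <- function(w, Tt) {
  d <- dim(w)
  aperm(array(w, c(d[1L], d[2L], Tt)), c(1L, 3L, 2L))
}

# contract (C, T, B) over time -> (C, B); adjoint of bc_time
sum_time <- function(x) {
  d <- dim(x)
  matrix(rowSums(matrix(aperm(x, c(1L, 3L, 2L)), d[1L] * d[3L], d[2L])), d[1L], d[3L])
}

# ---- backbone structure -----------------------------------------------------
make_backbone_desc <- function(prefix, c_in, stem_width, widths, counts, type) {
  blocks <- list()
  cur <- stem_width
  for (s in seq_along(widths)) {
    for (b in seq_len(counts[s])) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      out <- widths[s]
      blocks[[length(blocks) + 1L]] <- list(
        name = sprintf("%s.s%d.b%d", prefix, s, b),
        type = type, stage = s, stride = stride,
        c_in = cur, c_out = out,
        c_mid = if (type == "bottleneck") out %/% 4L else out,
        proj = (cur != out || stride != 1L))
      cur <- out
    }
  }
  list(prefix = prefix, c_in = c_in, stem_width = stem_width, blocks = blocks,
       out_width = cur)
}

reg_backbone <- function(net, desc) {
  pf <- desc$prefix
  reg_conv(net, paste0(pf, ".stem.conv"), desc$stem_width, desc$c_in, 7L)
  reg_bn(net, paste0(pf, ".stem.bn"), desc$stem_width)
  for (blk in desc$blocks) {
    nm <- blk$name
    if (blk$type == "bottleneck") {
      reg_conv(net, paste0(nm, ".conv1"), blk$c_mid, blk$c_in, 1L)
      reg_bn(net, paste0(nm, ".bn1"), blk$c_mid)
      reg_conv(net, paste0(nm, ".conv2"), blk$c_mid, blk$c_mid, 3L)
      reg_bn(net, paste0(nm, ".bn2"), blk$c_mid)
      reg_conv(net, paste0(nm, ".conv3"), blk$c_out, blk$c_mid, 1L)
      reg_bn(net, paste0(nm, ".bn3"), blk$c_out)
    } else {
      reg_conv(net, paste0(nm, ".conv1"), blk$c_out, blk$c_in, 3L)
      reg_bn(net, paste0(nm, ".bn1"), blk$c_out)
      reg_conv(net, paste0(nm, ".conv2"), blk$c_out, blk$c_out, 3L)
      reg_bn(net, paste0(nm, ".bn2"), blk$c_out)
    }
    if (blk$proj) {
      reg_conv(net, paste0(nm, ".proj.conv"), blk$c_out, blk$c_in, 1L)
      reg_bn(net, paste0(nm, ".proj.bn"), blk$c_out)
    }
  }
}

block_f <- function(net, ctx, blk, x) {
  nm <- blk$name
  if (blk$type == "bottleneck") {
    # 1x1 reduce -> 3x1 (carries the stride) -> 1x1 expand
    h <- bnrelu_f(net, ctx, paste0(nm, ".bn1"),
                  conv_f(net, ctx, paste0(nm, ".conv1"), x))
    h <- bnrelu_f(net, ctx, paste0(nm, ".bn2"),
                  conv_f(net, ctx, paste0(nm, ".conv2"), h, stride = blk$stride, pad = 1L))
    h <- bn_f(net, ctx, paste0(nm, ".bn3"),
              conv_f(net, ctx, paste0(nm, ".conv3"), h))
  } else {
    h <- bnrelu_f(net, ctx, paste0(nm, ".bn1"),
                  conv_f(net, ctx, paste0(nm, ".conv1"), x, stride = blk$stride, pad = 1L))
    h <- bn_f(net, ctx, paste0(nm, ".bn2"),
              conv_f(net, ctx, paste0(nm, ".conv2"), h, pad = 1L))
  }
  sc <- if (blk$proj) {
    bn_f(net, ctx, paste0(nm, ".proj.bn"),
         conv_f(net, ctx, paste0(nm, ".proj.conv"), x, stride = blk$stride))
  } else x
  relu_f(ctx, paste0(nm, ".ro"), h + sc)
}

block_b <- function(net, ctx, blk, dy) {
  nm <- blk$name
  dsum <- relu_b(ctx, paste0(nm, ".ro"), dy)
  if (blk$type == "bottleneck") {
    dh <- bn_b(net, ctx, paste0(nm, ".bn3"), dsum)
    dh <- conv_b(net, ctx, paste0(nm, ".conv3"), dh)
    dh <- bnrelu_b(net, ctx, paste0(nm, ".bn2"), dh)
    dh <- conv_b(net, ctx, paste0(nm, ".conv2"), dh)
    dh <- bnrelu_b(net, ctx, paste0(nm, ".bn1"), dh)
    dx_main <- conv_b(net, ctx, paste0(nm, ".conv1"), dh)
  } else {
    dh <- bn_b(net, ctx, paste0(nm, ".bn2"), dsum)
    dh <- conv_b(net, ctx, paste0(nm, ".conv2"), dh)
    dh <- bnrelu_b(net, ctx, paste0(nm, ".bn1"), dh)
    dx_main <- conv_b(net, ctx, paste0(nm, ".conv1"), dh)
  }
  dx_sc <- if (blk$proj) {
    conv_b(net, ctx, paste0(nm, ".proj.conv"),
           bn_b(net, ctx, paste0(nm, ".proj.bn"), dsum))
  } else dsum
  dx_main + dx_sc
}

backbone_f <- function(net, ctx, desc, x, record = NULL) {
  pf <- desc$prefix
  if (dim(x)[1L] != desc$c_in) {
    stopf("%s branch expects %d channels, got %d", pf, desc$c_in, dim(x)[1L])
  }
  if (dim(x)[2L] < 7L) stopf("input length %d shorter than the stem kernel", dim(x)[2L])
  h <- conv_f(net, ctx, paste0(pf, ".stem.conv"), x, stride = 2L, pad = 3L)
  h <- bnrelu_f(net, ctx, paste0(pf, ".stem.bn"), h)
  h <- pool_f(ctx, paste0(pf, ".stem.pool"), h)
  if (!is.null(record)) record[[paste0(pf, "_stem")]] <- h
  for (blk in desc$blocks) {
    h <- block_f(net, ctx, blk, h)
    if (!is.null(record)) record[[blk$name]] <- h
  }
  h
}

backbone_b <- function(net, ctx, desc, dy) {
  pf <- desc$prefix
  for (blk in rev(desc$blocks)) dy <- block_b(net, ctx, blk, dy)
  dy <- pool_b(ctx, paste0(pf, ".stem.pool"), dy)
  dy <- bnrelu_b(net, ctx, paste0(pf, ".stem.bn"), dy)
  conv_b(net, ctx, paste0(pf, ".stem.conv"), dy)
}

# ---- model construction -----------------------------------------------------

#' Build a fusion network
#'
#' Instantiates all parameters of the network described by a
#' [model_config()]: stems, residual backbones, branch projections, the
#' cross-channel fusion pathways, the gated temporal-channel attention block
#' and the classification head. Convolutions use Kaiming (fan-out) init,
#' batch norm starts at gamma = 1 / beta = 0, and the whole initialization is
#' a pure function of `seed`.
#'
#' @param config a [model_config()].
#' @param seed integer initialization seed.
#' @return an environment of class `fusion_net` holding `params` (named
#'   list of arrays), `bn` (running statistics), `config` and the backbone
#'   descriptors.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$grads <- list()
  net$bn <- list()
  net$config <- config
  net$seed <- as.integer(seed)
  with_seed(seed, {
    if (config$use_eeg) {
      net$eeg_desc <- make_backbone_desc("eeg", config$eeg_channels, config$stem_width,
                                         config$eeg_stage_widths, config$eeg_block_counts,
                                         "bottleneck")
      reg_backbone(net, net$eeg_desc)
      reg_conv(net, "eeg.proj", config$embed_dim, net$eeg_desc$out_width, 1L, bias = TRUE)
    }
    if (config$use_eog) {
      net$eog_desc <- make_backbone_desc("eog", config$eog_channels, config$stem_width,
                                         config$eog_stage_widths, config$eog_block_counts,
                                         "basic")
      reg_backbone(net, net$eog_desc)
      reg_conv(net, "eog.proj", config$embed_dim, net$eog_desc$out_width, 1L, bias = TRUE)
    }
    C <- config$embed_dim
    if (config$use_eeg && config$use_eog) {
      # both pathways are registered even when fusion is bypassed so that a
      # single parameter set supports every ablation switch
      reg_linear(net, "fus.eog2eeg.fc1", config$fusion_hidden, C)
      reg_linear(net, "fus.eog2eeg.fc2", C, config$fusion_hidden)
      reg_linear(net, "fus.eeg2eog.fc1", config$fusion_hidden, C)
      reg_linear(net, "fus.eeg2eog.fc2", C, config$fusion_hidden)
    }
    Cf <- config$fused_dim
    if (config$use_gtca) {
      reg_linear(net, "gtca.ta.fc1", config$ta_bottleneck, Cf)
      reg_linear(net, "gtca.ta.fc2", Cf, config$ta_bottleneck)
      reg_bn(net, "gtca.bn", Cf)
      reg_conv(net, "gtca.gate", Cf, Cf, 1L, bias = TRUE)
      reg_conv(net, "gtca.eca", 1L, 1L, config$eca_kernel)
    }
    reg_linear(net, "head.fc", config$n_classes, Cf)
  })
  class(net) <- c("fusion_net", "environment")
  net
}

#' @export
print.fusion_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<fusion_net: %d parameter arrays, %s parameters>\n",
              length(x$params), format(np, big.mark = ",")))
  print(x$config)
  invisible(x)
}

#' Number of trainable parameters
#' @param net a `fusion_net`.
#' @return integer count over all parameter arrays.
#' @export
model_num_params <- function(net) sum(vapply(net$params, length, 0L))

# ---- forward ----------------------------------------------------------------

#' Forward pass
#'
#' Runs the network on a batch. Inputs are channel-first arrays
#' `(channels, samples, batch)`; EEG and EOG must share the temporal length
#' (use [harmonize_rates()] for mixed-rate profiles). In eval mode
#' (`train = FALSE`) batch norm uses running statistics and the pass is
#' deterministic.
#'
#' `keep_intermediates` records every quantity later analyses need: branch
#' embeddings (the first two Grad-CAM tap points), fusion weights, modulated
#' branch features, the fused map, temporal/gate/ECA attention weights and
#' the refined output map (the third tap point), plus per-stage backbone
#' outputs for shape audits.
#'
#' @param net a `fusion_net`.
#' @param eeg,eog input arrays `(C, L, B)`; either may be `NULL` when the
#'   corresponding branch is disabled.
#' @param train logical; `TRUE` uses batch statistics and updates running
#'   moments.
#' @param keep_intermediates logical; record intermediate feature maps.
#' @param use_fusion,use_gtca optional overrides of the config's ablation
#'   switches (documented bypass: `use_fusion = FALSE` sets all fusion
#'   weights to one, `use_gtca = FALSE` makes the attention block the
#'   identity).
#' @return list with `logits` (classes x batch), `probs` (softmax, columns
#'   sum to one), `intermediates` (when requested) and `ctx` (opaque cache
#'   consumed by [model_backward()]).
#' @export
model_forward <- function(net, eeg = NULL, eog = NULL, train = FALSE,
                          keep_intermediates = FALSE,
                          use_fusion = NULL, use_gtca = NULL) {
  cfg <- net$config
  use_fusion <- use_fusion %||% cfg$use_fusion
  use_gtca <- use_gtca %||% cfg$use_gtca
  ctx <- new.env(parent = emptyenv())
  ctx$cache <- list()
  ctx$train <- isTRUE(train)
  ctx$use_fusion <- use_fusion
  ctx$use_gtca <- use_gtca
  ctx$v <- list()
  inter <- if (keep_intermediates) list() else NULL
  rec <- if (keep_intermediates) new.env() else NULL

  f_eeg <- f_eog <- NULL
  if (cfg$use_eeg) {
    if (is.null(eeg)) stopf("config uses the EEG branch but no EEG input given")
    s4 <- backbone_f(net, ctx, net$eeg_desc, eeg, record = rec)
    f_eeg <- conv_f(net, ctx, "eeg.proj", s4)
    ctx$v$f_eeg <- f_eeg
  }
  if (cfg$use_eog) {
    if (is.null(eog)) stopf("config uses the EOG branch but no EOG input given")
    s4 <- backbone_f(net, ctx, net$eog_desc, eog, record = rec)
    f_eog <- conv_f(net, ctx, "eog.proj", s4)
    ctx$v$f_eog <- f_eog
  }
  if (cfg$use_eeg && cfg$use_eog) {
    if (!identical(dim(f_eeg)[2L], dim(f_eog)[2L])) {
      stopf("EEG and EOG feature maps disagree in time (%d vs %d); harmonize sampling rates first",
            dim(f_eeg)[2L], dim(f_eog)[2L])
    }
    C <- cfg$embed_dim
    Tt <- dim(f_eeg)[2L]
    B <- dim(f_eeg)[3L]
    if (use_fusion) {
      z_eeg <- gap_f(ctx, "fus.gap.eeg", f_eeg)
      z_eog <- gap_f(ctx, "fus.gap.eog", f_eog)
      # each branch is rescaled by a gate computed from the OTHER branch
      w_eog2eeg <- sigm_f(ctx, "fus.eog2eeg.sig",
                          lin_f(net, ctx, "fus.eog2eeg.fc2",
                                relu_f(ctx, "fus.eog2eeg.relu",
                                       lin_f(net, ctx, "fus.eog2eeg.fc1", z_eog))))
      w_eeg2eog <- sigm_f(ctx, "fus.eeg2eog.sig",
                          lin_f(net, ctx, "fus.eeg2eog.fc2",
                                relu_f(ctx, "fus.eeg2eog.relu",
                                       lin_f(net, ctx, "fus.eeg2eog.fc1", z_eeg))))
      w1b <- bc_time(w_eog2eeg, Tt)
      w2b <- bc_time(w_eeg2eog, Tt)
      fbar_eeg <- f_eeg * w1b
      fbar_eog <- f_eog * w2b
      ctx$v$w1b <- w1b
      ctx$v$w2b <- w2b
      if (keep_intermediates) {
        inter$w_eog2eeg <- w_eog2eeg
        inter$w_eeg2eog <- w_eeg2eog
      }
    } else {
      fbar_eeg <- f_eeg
      fbar_eog <- f_eog
    }
    ff <- array(0, c(2L * C, Tt, B))
    ff[seq_len(C), , ] <- fbar_eeg         # EEG first in the concatenation
    ff[C + seq_len(C), , ] <- fbar_eog
    if (keep_intermediates) {
      inter$fbar_eeg <- fbar_eeg
      inter$fbar_eog <- fbar_eog
      inter$f_fused <- ff
    }
  } else {
    ff <- if (cfg$use_eeg) f_eeg else f_eog
  }

  if (use_gtca) {
    if (!cfg$use_gtca) stopf("gtca parameters were not built for this config")
    Cf <- cfg$fused_dim
    Tt <- dim(ff)[2L]
    z <- gap_f(ctx, "gtca.gap", ff)
    a <- sigm_f(ctx, "gtca.ta.sig",
                lin_f(net, ctx, "gtca.ta.fc2",
                      relu_f(ctx, "gtca.ta.relu",
                             lin_f(net, ctx, "gtca.ta.fc1", z))))
    ab <- bc_time(a, Tt)
    f_temp <- bn_f(net, ctx, "gtca.bn", ff * ab + ff)
    g <- sigm_f(ctx, "gtca.gate.sig", conv_f(net, ctx, "gtca.gate", ff))
    f_gate <- g * ff + (1 - g) * f_temp
    zg <- gap_f(ctx, "gtca.eca.gap", f_gate)
    zr <- zg
    dim(zr) <- c(1L, Cf, dim(zg)[2L])       # channel axis becomes "time"
    pad_eca <- (cfg$eca_kernel - 1L) %/% 2L
    w_eca <- sigm_f(ctx, "gtca.eca.sig",
                    conv_f(net, ctx, "gtca.eca", zr, pad = pad_eca))
    dim(w_eca) <- c(Cf, dim(zg)[2L])
    web <- bc_time(w_eca, Tt)
    Fout <- if (cfg$eca_residual_add) f_gate + web else f_gate * web
    ctx$v$ab <- ab
    ctx$v$ff <- ff
    ctx$v$f_temp <- f_temp
    ctx$v$g <- g
    ctx$v$f_gate <- f_gate
    ctx$v$web <- web
    if (keep_intermediates) {
      inter$a <- a
      inter$g <- g
      inter$eca_w <- w_eca
      inter$f_temp <- f_temp
      inter$f_gate <- f_gate
    }
  } else {
    Fout <- ff
  }
  ctx$v$Fout <- Fout
  if (keep_intermediates) inter$F <- Fout

  h <- gap_f(ctx, "head.gap", Fout)
  logits <- lin_f(net, ctx, "head.fc", h)
  probs <- softmax_cols(logits)
  if (keep_intermediates) {
    inter$f_eeg <- f_eeg
    inter$f_eog <- f_eog
    for (nm in ls(rec)) inter[[nm]] <- rec[[nm]]
  }
  list(logits = logits, probs = probs, intermediates = inter, ctx = ctx)
}

# ---- backward ---------------------------------------------------------------

#' Backward pass
#'
#' Backpropagates `dlogits` through the cached forward context, accumulating
#' parameter gradients into `net$grads` (zeroed on entry). Optionally returns
#' the gradients arriving at the three saliency tap points: the EEG branch
#' embedding, the EOG branch embedding and the refined output of the
#' attention block.
#'
#' @param net a `fusion_net`.
#' @param ctx the `ctx` element returned by [model_forward()].
#' @param dlogits upstream gradient, same shape as the logits.
#' @param tap_grads logical; also return tap-point gradients.
#' @return invisibly, a list of tap gradients (`eeg_embed`, `eog_embed`,
#'   `gtca_out`) when requested.
#' @export
model_backward <- function(net, ctx, dlogits, tap_grads = FALSE) {
  cfg <- net$config
  net$grads <- list()
  taps <- list()
  dh <- lin_b(net, ctx, "head.fc", dlogits)
  dF <- gap_b(ctx, "head.gap", dh)
  if (tap_grads) taps$gtca_out <- dF

  if (ctx$use_gtca) {
    v <- ctx$v
    if (cfg$eca_residual_add) {
      df_gate <- dF
      dweca <- sum_time(dF)
    } else {
      df_gate <- dF * v$web
      dweca <- sum_time(dF * v$f_gate)
    }
    Cf <- cfg$fused_dim
    B <- dim(dweca)[2L]
    dwr <- dweca
    dim(dwr) <- c(1L, Cf, B)
    dzr <- conv_b(net, ctx, "gtca.eca", sigm_b(ctx, "gtca.eca.sig", dwr))
    dzg <- dzr
    dim(dzg) <- c(Cf, B)
    df_gate <- df_gate + gap_b(ctx, "gtca.eca.gap", dzg)
    # f_gate = g*ff + (1-g)*f_temp
    dg <- df_gate * (v$ff - v$f_temp)
    dff <- df_gate * v$g
    df_temp <- df_gate * (1 - v$g)
    dff <- dff + conv_b(net, ctx, "gtca.gate", sigm_b(ctx, "gtca.gate.sig", dg))
    du <- bn_b(net, ctx, "gtca.bn", df_temp)
    dff <- dff + du * (1 + v$ab)
    da <- sum_time(du * v$ff)
    dz <- lin_b(net, ctx, "gtca.ta.fc1",
                relu_b(ctx, "gtca.ta.relu",
                       lin_b(net, ctx, "gtca.ta.fc2",
                             sigm_b(ctx, "gtca.ta.sig", da))))
    dff <- dff + gap_b(ctx, "gtca.gap", dz)
  } else {
    dff <- dF
  }

  if (cfg$use_eeg && cfg$use_eog) {
    C <- cfg$embed_dim
    dfbar_eeg <- dff[seq_len(C), , , drop = FALSE]
    dfbar_eog <- dff[C + seq_len(C), , , drop = FALSE]
    if (ctx$use_fusion) {
      v <- ctx$v
      df_eeg <- dfbar_eeg * v$w1b
      df_eog <- dfbar_eog * v$w2b
      dw1 <- sum_time(dfbar_eeg * v$f_eeg)
      dw2 <- sum_time(dfbar_eog * v$f_eog)
      dz_eog <- lin_b(net, ctx, "fus.eog2eeg.fc1",
                      relu_b(ctx, "fus.eog2eeg.relu",
                             lin_b(net, ctx, "fus.eog2eeg.fc2",
                                   sigm_b(ctx, "fus.eog2eeg.sig", dw1))))
      dz_eeg <- lin_b(net, ctx, "fus.eeg2eog.fc1",
                      relu_b(ctx, "fus.eeg2eog.relu",
                             lin_b(net, ctx, "fus.eeg2eog.fc2",
                                   sigm_b(ctx, "fus.eeg2eog.sig", dw2))))
      df_eog <- df_eog + gap_b(ctx, "fus.gap.eog", dz_eog)
      df_eeg <- df_eeg + gap_b(ctx, "fus.gap.eeg", dz_eeg)
    } else {
      df_eeg <- dfbar_eeg
      df_eog <- dfbar_eog
    }
  } else if (cfg$use_eeg) {
    df_eeg <- dff
    df_eog <- NULL
  } else {
    df_eeg <- NULL
    df_eog <- dff
  }

  if (cfg$use_eeg) {
    if (tap_grads) taps$eeg_embed <- df_eeg
    ds4 <- conv_b(net, ctx, "eeg.proj", df_eeg)
    backbone_b(net, ctx, net$eeg_desc, ds4)
  }
  if (cfg$use_eog) {
    if (tap_grads) taps$eog_embed <- df_eog
    ds4 <- conv_b(net, ctx, "eog.proj", df_eog)
    backbone_b(net, ctx, net$eog_desc, ds4)
  }
  invisible(taps)
}

# ---- checkpoints ------------------------------------------------------------

#' Snapshot / restore model state
#'
#' A checkpoint stores parameters, batch-norm running statistics, the config
#' and the build seed; restoring overwrites the network state in place.
#'
#' @param net a `fusion_net`.
#' @param checkpoint a list produced by `model_checkpoint()`.
#' @return `model_checkpoint` returns the checkpoint list; `model_restore`
#'   returns `net` invisibly.
#' @export
model_checkpoint <- function(net) {
  list(params = net$params, bn = net$bn, config = net$config, seed = net$seed)
}

#' @rdname model_checkpoint
#' @export
model_restore <- function(net, checkpoint) {
  stopifnot(identical(sort(names(net$params)), sort(names(checkpoint$params))))
  net$params <- checkpoint$params
  net$bn <- checkpoint$bn
  invisible(net)
}

#' Predict sleep stages for a dataset
#'
#' Runs eval-mode forward passes in batches and returns the class
#' probabilities and hard labels.
#'
#' @param net a `fusion_net` (trained or not).
#' @param dataset an `epoch_dataset`.
#' @param indices optional epoch subset.
#' @param batch_size batch size for the forward passes.
#' @return list with `probs` (N x classes) and `labels` (integer 0..4).
#' @export
model_predict <- function(net, dataset, indices = NULL, batch_size = 32L) {
  idx <- indices %||% seq_len(n_epochs(dataset))
  K <- net$config$n_classes
  probs <- matrix(NA_real_, length(idx), K)
  pos <- 1L
  while (pos <= length(idx)) {
    take <- idx[pos:min(pos + batch_size - 1L, length(idx))]
    b <- dataset_batch(dataset, take)
    out <- model_forward(net,
                         eeg = if (net$config$use_eeg) b$eeg else NULL,
                         eog = if (net$config$use_eog) b$eog else NULL,
                         train = FALSE)
    probs[pos:(pos + length(take) - 1L), ] <- t(out$probs)
    pos <- pos + length(take)
  }
  list(probs = probs, labels = max.col(probs) - 1L)
}
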