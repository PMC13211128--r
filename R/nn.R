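# Minimal 1-D neural-network primitives with hand-written backward passes.
#
# There is no deep-learning framework in the supported stack, so the few
# layer types the architecture needs are implemented directly. Feature maps
# are arrays of dim (channels, time, batch); channel-first layout makes
# per-channel broadcasts plain recycling. The hot kernels (conv, pooling,
# batch norm, ReLU) run in C++ (src/nn_kernels.cpp); bit-compatible pure-R
# reference implementations (r_* below) remain the independent oracle for
# the kernel tests, and all backward passes are additionally verified
# against finite differences.

# ---- conv1d ----------------------------------------------------------------
# W: (C_out, C_in, k); x: (C, T, B). Output length floor((T+2p-k)/s)+1.
conv1d_forward <- function(x, W, b = NULL, stride = 1L, pad = 0L) {
  d <- dim(x)
  kd <- dim(W)
  if (kd[2L] != d[1L]) stopf("conv1d: input has %d channels, weight expects %d", d[1L], kd[2L])
  Tout <- (d[2L] + 2L * pad - kd[3L]) %/% stride + 1L
  if (Tout < 1L) stopf("conv1d: input length %d too short for kernel %d", d[2L], kd[3L])
  out <- cpp_conv1d_forward(x, W, b, stride, pad)
  list(out = out, cache = list(x = x, stride = stride, pad = pad,
                               has_bias = !is.null(b)))
}

conv1d_backward <- function(dy, cache, W) {
  r <- cpp_conv1d_backward(dy, cache$x, W, cache$stride, cache$pad, cache$has_bias)
  list(dx = r$dx, dW = r$dW, db = r$db)
}

# Pure-R reference (oracle for the C++ kernels).
r_conv1d_forward <- function(x, W, b = NULL, stride = 1L, pad = 0L) {
  d <- dim(x)
  C_in <- d[1L]; L <- d[2L]; B <- d[3L]
  kd <- dim(W)
  C_out <- kd[1L]; k <- kd[3L]
  Tout <- (L + 2L * pad - k) %/% stride + 1L
  if (pad > 0L) {
    xp <- array(0, c(C_in, L + 2L * pad, B))
    xp[, pad + seq_len(L), ] <- x
  } else xp <- x
  base <- stride * (seq_len(Tout) - 1L)
  ym <- matrix(0, C_out, Tout * B)
  for (j in seq_len(k)) {
    xs <- xp[, j + base, , drop = FALSE]
    dim(xs) <- c(C_in, Tout * B)
    Wj <- W[, , j, drop = FALSE]
    dim(Wj) <- c(C_out, C_in)
    ym <- ym + Wj %*% xs
  }
  if (!is.null(b)) ym <- ym + b
  dim(ym) <- c(C_out, Tout, B)
  ym
}

r_conv1d_backward <- function(dy, x, W, stride = 1L, pad = 0L, has_bias = FALSE) {
  kd <- dim(W); C_out <- kd[1L]; C_in <- kd[2L]; k <- kd[3L]
  L <- dim(x)[2L]; B <- dim(x)[3L]
  Tout <- dim(dy)[2L]
  if (pad > 0L) {
    xp <- array(0, c(C_in, L + 2L * pad, B))
    xp[, pad + seq_len(L), ] <- x
  } else xp <- x
  base <- stride * (seq_len(Tout) - 1L)
  dym <- dy
  dim(dym) <- c(C_out, Tout * B)
  dxp <- array(0, dim(xp))
  dW <- array(0, kd)
  for (j in seq_len(k)) {
    xs <- xp[, j + base, , drop = FALSE]
    dim(xs) <- c(C_in, Tout * B)
    dW[, , j] <- tcrossprod(dym, xs)
    Wj <- W[, , j, drop = FALSE]
    dim(Wj) <- c(C_out, C_in)
    contrib <- crossprod(Wj, dym)
    dim(contrib) <- c(C_in, Tout, B)
    dxp[, j + base, ] <- dxp[, j + base, , drop = FALSE] + contrib
  }
  dx <- if (pad > 0L) dxp[, pad + seq_len(L), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = if (has_bias) rowSums(dym) else NULL)
}

# ---- batch norm (per channel over time x batch) ----------------------------
bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       train = TRUE, momentum = 0.1, eps = 1e-5) {
  C <- dim(x)[1L]
  n <- length(x) / C
  r <- cpp_bn_forward(x, gamma, beta, running_mean, running_var, train, eps)
  if (train) {
    unb <- if (n > 1) n / (n - 1) else 1
    new_rm <- (1 - momentum) * running_mean + momentum * as.numeric(r$mean)
    new_rv <- (1 - momentum) * running_var + momentum * as.numeric(r$var) * unb
  } else {
    new_rm <- running_mean
    new_rv <- running_var
  }
  list(out = r$out,
       cache = list(xhat = r$xhat, invstd = as.numeric(r$invstd),
                    gamma = gamma, train = train, C = C),
       running_mean = new_rm, running_var = new_rv)
}

bn_backward <- function(dy, cache) {
  r <- cpp_bn_backward(dy, cache$xhat, cache$invstd, cache$gamma, cache$train)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

# Fused batch-norm + ReLU (single pass; the backbones' inner pattern).
bnrelu_forward <- function(x, gamma, beta, running_mean, running_var,
                           train = TRUE, momentum = 0.1, eps = 1e-5) {
  C <- dim(x)[1L]
  n <- length(x) / C
  r <- cpp_bnrelu_forward(x, gamma, beta, running_mean, running_var, train, eps)
  if (train) {
    unb <- if (n > 1) n / (n - 1) else 1
    new_rm <- (1 - momentum) * running_mean + momentum * as.numeric(r$mean)
    new_rv <- (1 - momentum) * running_var + momentum * as.numeric(r$var) * unb
  } else {
    new_rm <- running_mean
    new_rv <- running_var
  }
  list(out = r$out,
       cache = list(out = r$out, xhat = r$xhat, invstd = as.numeric(r$invstd),
                    gamma = gamma, train = train),
       running_mean = new_rm, running_var = new_rv)
}

bnrelu_backward <- function(dy, cache) {
  r <- cpp_bnrelu_backward(dy, cache$out, cache$xhat, cache$invstd,
                           cache$gamma, cache$train)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

r_bn_forward <- function(x, gamma, beta, running_mean, running_var,
                         train = TRUE, eps = 1e-5) {
  C <- dim(x)[1L]
  if (train) {
    xm <- matrix(x, nrow = C)
    m <- rowMeans(xm)
    v <- rowMeans(xm * xm) - m * m
    v[v < 0] <- 0
  } else {
    m <- running_mean
    v <- running_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (x - m) * invstd      # recycling over the channel (first) dim
  list(out = gamma * xhat + beta, xhat = xhat, mean = m, var = v, invstd = invstd)
}

r_bn_backward <- function(dy, xhat, invstd, gamma, train = TRUE) {
  C <- dim(dy)[1L]
  dym <- matrix(dy, nrow = C)
  dgamma <- rowSums(dym * matrix(xhat, nrow = C))
  dbeta <- rowSums(dym)
  dxhat <- dy * gamma
  if (train) {
    mdx <- rowMeans(matrix(dxhat, nrow = C))
    mdxx <- rowMeans(matrix(dxhat * xhat, nrow = C))
    dx <- invstd * (dxhat - mdx - xhat * mdxx)
  } else {
    dx <- dxhat * invstd
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- elementwise activations ----------------------------------------------
relu_forward <- function(x) {
  if (length(dim(x)) == 3L) list(out = cpp_relu_forward(x), cache = x)
  else list(out = x * (x > 0), cache = x)   # 2-D descriptor pathways
}
relu_backward <- function(dy, cache) {
  if (length(dim(dy)) == 3L) cpp_relu_backward(dy, cache)
  else dy * (cache > 0)
}

sigmoid_forward <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(out = y, cache = y)
}
sigmoid_backward <- function(dy, cache) dy * cache * (1 - cache)

# ---- max pooling -----------------------------------------------------------
maxpool1d_forward <- function(x, k = 3L, stride = 2L, pad = 1L) {
  r <- cpp_maxpool1d_forward(x, k, stride, pad)
  list(out = r$out, cache = list(arg = r$arg, k = k, stride = stride,
                                 pad = pad, L = dim(x)[2L]))
}

maxpool1d_backward <- function(dy, cache) {
  cpp_maxpool1d_backward(dy, cache$arg, cache$L, cache$k, cache$stride, cache$pad)
}

r_maxpool1d_forward <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  C <- d[1L]; L <- d[2L]; B <- d[3L]
  Tout <- (L + 2L * pad - k) %/% stride + 1L
  if (pad > 0L) {
    xp <- array(-Inf, c(C, L + 2L * pad, B))
    xp[, pad + seq_len(L), ] <- x
  } else xp <- x
  base <- stride * (seq_len(Tout) - 1L)
  cur <- xp[, 1L + base, , drop = FALSE]
  arg <- array(0L, c(C, Tout, B))
  for (j in seq.int(2L, k)) {
    xs <- xp[, j + base, , drop = FALSE]
    m <- xs > cur
    cur[m] <- xs[m]
    arg[m] <- j - 1L
  }
  list(out = cur, arg = arg)
}

# ---- global average pool over time ----------------------------------------
# (C, T, B) -> (C, B)
gap_time_forward <- function(x) {
  d <- dim(x)
  C <- d[1L]; Tt <- d[2L]; B <- d[3L]
  xm <- matrix(aperm(x, c(1L, 3L, 2L)), C * B, Tt)
  y <- matrix(rowMeans(xm), C, B)
  list(out = y, cache = list(C = C, Tt = Tt, B = B))
}

gap_time_backward <- function(dy, cache) {
  aperm(array(dy / cache$Tt, c(cache$C, cache$B, cache$Tt)), c(1L, 3L, 2L))
}

# ---- linear ----------------------------------------------------------------
linear_forward <- function(x, W, b = NULL) {
  y <- W %*% x
  if (!is.null(b)) y <- y + b
  list(out = y, cache = x)
}

linear_backward <- function(dy, cache, W, has_bias = TRUE) {
  list(dx = crossprod(W, dy),
       dW = tcrossprod(dy, cache),
       db = if (has_bias) rowSums(dy) else NULL)
}

# ---- softmax / cross-entropy ----------------------------------------------
softmax_cols <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

# labels: integer 0..K-1; returns mean cross-entropy and dlogits.
cross_entropy <- function(logits, labels) {
  B <- ncol(logits)
  p <- softmax_cols(logits)
  idx <- cbind(labels + 1L, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, dlogits = d / B, probs = p)
}

# ---- parameter init --------------------------------------------------------
# Kaiming fan-out init for conv weights (matches common residual-net practice).
init_conv <- function(c_out, c_in, k, bias = FALSE) {
  sd <- sqrt(2 / (c_out * k))
  W <- array(stats::rnorm(c_out * c_in * k, sd = sd), c(c_out, c_in, k))
  out <- list(W = W)
  if (bias) out$b <- numeric(c_out)
  out
}

init_linear <- function(n_out, n_in) {
  bound <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_out * n_in, -bound, bound), n_out, n_in),
       b = numeric(n_out))
}

init_bn <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C))
}

# ---- Adam optimizer --------------------------------------------------------
# Classic Adam-with-L2: weight decay is added to the raw gradient before the
# moment updates. Parameters whose gradient is NULL (unused branches under
# ablation switches) are skipped.
adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    m <- state$m[[nm]]
    v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = state)
}
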