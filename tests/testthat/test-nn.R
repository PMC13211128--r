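# Layer primitives: the C++ kernels against their pure-R references, and
# every backward pass against central finite differences.

test_that("C++ kernels agree with the pure-R reference implementations", {
  set.seed(42)
  x <- rand_map(5, 23, 4, seed = 42)
  W <- array(rnorm(7 * 5 * 3), c(7, 5, 3))
  b <- rnorm(7)
  for (stride in c(1L, 2L)) {
    for (pad in c(0L, 1L)) {
      got <- conv1d_forward(x, W, b, stride, pad)$out
      ref <- r_conv1d_forward(x, W, b, stride, pad)
      expect_equal(got, ref, tolerance = 1e-12)
      dy <- array(rnorm(length(got)), dim(got))
      gb <- conv1d_backward(dy, list(x = x, stride = stride, pad = pad,
                                     has_bias = TRUE), W)
      rb <- r_conv1d_backward(dy, x, W, stride, pad, has_bias = TRUE)
      expect_equal(gb$dx, rb$dx, tolerance = 1e-12)
      expect_equal(gb$dW, rb$dW, tolerance = 1e-12)
      expect_equal(as.numeric(gb$db), rb$db, tolerance = 1e-12)
    }
  }
  # batch norm (train mode)
  gamma <- runif(5, 0.5, 1.5); beta <- rnorm(5)
  got <- bn_forward(x, gamma, beta, numeric(5), rep(1, 5), train = TRUE)
  ref <- r_bn_forward(x, gamma, beta, numeric(5), rep(1, 5), train = TRUE)
  expect_equal(got$out, ref$out, tolerance = 1e-12)
  expect_equal(got$cache$xhat, ref$xhat, tolerance = 1e-12)
  dy <- array(rnorm(length(x)), dim(x))
  gb <- bn_backward(dy, got$cache)
  rb <- r_bn_backward(dy, ref$xhat, ref$invstd, gamma, train = TRUE)
  expect_equal(gb$dx, rb$dx, tolerance = 1e-12)
  expect_equal(gb$dgamma, rb$dgamma, tolerance = 1e-12)
  # fused bn+relu equals bn then relu
  fu <- bnrelu_forward(x, gamma, beta, numeric(5), rep(1, 5), train = TRUE)
  expect_equal(fu$out, pmax(ref$out, 0), tolerance = 1e-12)
  fb <- bnrelu_backward(dy, fu$cache)
  rb2 <- r_bn_backward(dy * (ref$out > 0), ref$xhat, ref$invstd, gamma, TRUE)
  expect_equal(fb$dx, rb2$dx, tolerance = 1e-12)
  # max pooling
  gp <- maxpool1d_forward(x)
  rp <- r_maxpool1d_forward(x)
  expect_equal(gp$out, rp$out, tolerance = 1e-12)
  expect_equal(as.integer(gp$cache$arg), as.integer(rp$arg))
})

test_that("composite chain gradients match finite differences", {
  set.seed(7)
  C <- 2L; L <- 40L; B <- 2L
  x <- rand_map(C, L, B, seed = 7)
  W <- array(rnorm(4 * C * 7, sd = 0.3), c(4, C, 7))
  gamma <- runif(4, 0.5, 1.5); beta <- rnorm(4)
  loss <- function(W, gamma, beta) {
    c1 <- conv1d_forward(x, W, NULL, 2L, 3L)
    b1 <- bn_forward(c1$out, gamma, beta, numeric(4), rep(1, 4), train = TRUE)
    r1 <- relu_forward(b1$out)
    p1 <- maxpool1d_forward(r1$out)
    sum(p1$out^2) / 2
  }
  c1 <- conv1d_forward(x, W, NULL, 2L, 3L)
  b1 <- bn_forward(c1$out, gamma, beta, numeric(4), rep(1, 4), train = TRUE)
  r1 <- relu_forward(b1$out)
  p1 <- maxpool1d_forward(r1$out)
  dr <- maxpool1d_backward(p1$out, p1$cache)
  db <- relu_backward(dr, r1$cache)
  bb <- bn_backward(db, b1$cache)
  cb <- conv1d_backward(bb$dx, c1$cache, W)
  eps <- 1e-6
  for (i in sample(length(W), 8)) {
    Wp <- W; Wp[i] <- W[i] + eps
    Wm <- W; Wm[i] <- W[i] - eps
    fd <- (loss(Wp, gamma, beta) - loss(Wm, gamma, beta)) / (2 * eps)
    expect_equal(cb$dW[i], fd, tolerance = 1e-5)
  }
  for (i in 1:4) {
    gp <- gamma; gp[i] <- gamma[i] + eps
    gm <- gamma; gm[i] <- gamma[i] - eps
    fd <- (loss(W, gp, beta) - loss(W, gm, beta)) / (2 * eps)
    expect_equal(bb$dgamma[i], fd, tolerance = 1e-5)
  }
})

test_that("softmax cross-entropy gradient and probabilities are consistent", {
  set.seed(3)
  logits <- matrix(rnorm(5 * 6, sd = 2), 5, 6)
  y <- sample(0:4, 6, replace = TRUE)
  ce <- cross_entropy(logits, y)
  expect_equal(colSums(ce$probs), rep(1, 6), tolerance = 1e-12)
  eps <- 1e-6
  for (i in sample(length(logits), 6)) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    fd <- (cross_entropy(lp, y)$loss - cross_entropy(lm, y)$loss) / (2 * eps)
    expect_equal(ce$dlogits[i], fd, tolerance = 1e-5)
  }
})

test_that("adam with zero learning rate leaves parameters unchanged", {
  p <- list(a = matrix(rnorm(4), 2), b = rnorm(3))
  g <- list(a = matrix(rnorm(4), 2), b = rnorm(3))
  st <- adam_step(p, g, adam_init(), lr = 0, weight_decay = 1e-4)
  expect_identical(st$params$a, p$a)
  expect_identical(st$params$b, p$b)
})
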