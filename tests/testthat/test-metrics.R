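# Confusion-matrix metrics against brute-force oracles.

brute_confusion <- function(yt, yp) {
  cm <- matrix(0L, 5, 5)
  for (i in seq_along(yt)) cm[yt[i] + 1L, yp[i] + 1L] <- cm[yt[i] + 1L, yp[i] + 1L] + 1L
  cm
}

test_that("confusion matrix matches an independent tally", {
  set.seed(10)
  yt <- sample(0:4, 1000, replace = TRUE)
  yp <- sample(0:4, 1000, replace = TRUE)
  expect_equal(unclass(confusion(yt, yp)), brute_confusion(yt, yp),
               ignore_attr = TRUE)
  expect_true(all(diag(confusion(yt, yt)) == tabulate(yt + 1L, 5)))
  cm1 <- confusion(2L, 3L)
  expect_equal(sum(cm1), 1L)
  expect_equal(cm1["N2", "N3"], 1L, ignore_attr = TRUE)
  expect_error(confusion(c(0, 9), c(0, 0)), "out of range")
})

test_that("OA, kappa and MF1 match brute-force computations to 1e-12", {
  set.seed(11)
  for (rep in 1:5) {
    yt <- sample(0:4, 1000, replace = TRUE)
    yp <- ifelse(runif(1000) < 0.6, yt, sample(0:4, 1000, replace = TRUE))
    cm <- confusion(yt, yp)
    # vector oracle for OA
    expect_equal(overall_accuracy(cm), 100 * mean(yt == yp), tolerance = 1e-12)
    # marginal-product oracle for kappa
    n <- length(yt)
    p0 <- mean(yt == yp)
    pe <- sum(vapply(0:4, function(c) mean(yt == c) * mean(yp == c), 0))
    expect_equal(cohens_kappa(cm), (p0 - pe) / (1 - pe), tolerance = 1e-12)
    # per-class oracle for MF1
    f1 <- vapply(0:4, function(c) {
      tp <- sum(yt == c & yp == c)
      prec <- if (sum(yp == c) > 0) tp / sum(yp == c) else 0
      rec <- if (sum(yt == c) > 0) tp / sum(yt == c) else 0
      if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }, 0)
    expect_equal(macro_f1(cm), mean(f1), tolerance = 1e-12)
  }
})

test_that("kappa limit cases behave", {
  yt <- rep(0:4, each = 10)
  expect_equal(cohens_kappa(confusion(yt, yt)), 1)
  # constant majority-class prediction: P0 = Pe = prevalence -> kappa 0
  yt2 <- c(rep(0L, 60), rep(1L, 10), rep(2L, 10), rep(3L, 10), rep(4L, 10))
  expect_equal(cohens_kappa(confusion(yt2, rep(0L, 100))), 0, tolerance = 1e-12)
  # 2x2 worked case, two computation routes
  cm2 <- matrix(c(20L, 10L, 5L, 15L), 2, 2)
  class(cm2) <- c("confusion_matrix", class(cm2))
  p0 <- 35 / 50
  pe <- (25 / 50) * (30 / 50) + (25 / 50) * (20 / 50)
  expect_equal(cohens_kappa(cm2), (p0 - pe) / (1 - pe), tolerance = 1e-12)
})

test_that("metric invariances hold", {
  set.seed(12)
  yt <- sample(0:4, 400, replace = TRUE)
  yp <- sample(0:4, 400, replace = TRUE)
  perm <- sample(400)
  for (f in list(overall_accuracy, cohens_kappa, macro_f1)) {
    expect_equal(f(confusion(yt, yp)), f(confusion(yt[perm], yp[perm])),
                 tolerance = 1e-12)
  }
  # kappa invariant under simultaneous row/column permutation
  cm <- unclass(confusion(yt, yp))
  pr <- sample(5)
  cmp <- cm[pr, pr]
  class(cmp) <- class(cm) <- c("confusion_matrix", "matrix")
  expect_equal(cohens_kappa(cm), cohens_kappa(cmp), tolerance = 1e-12)
  # kappa = 1 iff diagonal
  expect_true(cohens_kappa(confusion(yt, yt)) == 1)
  expect_lt(cohens_kappa(confusion(yt, yp)), 1)
  # MF1 bounded by the per-class extremes
  rep <- metrics_report(yt, yp)
  expect_gte(rep$MF1, min(rep$per_class$f1))
  expect_lte(rep$MF1, max(rep$per_class$f1))
})

test_that("absent classes contribute zero F1 with a warning", {
  yt <- rep(c(0L, 1L), 20)
  yp <- rep(c(0L, 1L), 20)
  cm <- confusion(yt, yp)
  expect_warning(m <- macro_f1(cm), "absent")
  expect_equal(m, 2 / 5)
})
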