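# Fold construction, checkpoint selection and the cross-validation harness
# (network trainings themselves are exercised in the acceptance suite).

test_that("stratified folds are balanced, exhaustive and reproducible", {
  labels <- rep(0:4, each = 20)
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_equal(length(f$test_idx), 20L)
    # exactly 4 of each class per fold under exact divisibility
    expect_true(all(tabulate(labels[f$test_idx] + 1L, 5) == 4L))
    expect_length(intersect(f$train_idx, f$test_idx), 0L)
  }
  all_test <- sort(unlist(lapply(folds, `[[`, "test_idx")))
  expect_identical(all_test, seq_along(labels))
  folds2 <- stratified_kfold(labels, k = 5, seed = 1)
  expect_identical(folds, folds2)
  # proportions within one sample also for awkward counts
  labels3 <- c(rep(0L, 23), rep(1L, 31), rep(2L, 46), rep(3L, 7), rep(4L, 13))
  folds3 <- stratified_kfold(labels3, k = 5, seed = 2)
  sizes <- lengths(lapply(folds3, `[[`, "test_idx"))
  expect_lte(diff(range(sizes)), 1L)
  for (cl in 0:4) {
    per_fold <- vapply(folds3, function(f) sum(labels3[f$test_idx] == cl), 0L)
    expect_lte(diff(range(per_fold)), 1L)
  }
  expect_error(stratified_kfold(c(rep(0L, 50), rep(4L, 3)), k = 5), "REM")
})

test_that("subject-aware folds partition subjects", {
  labels <- rep(0:4, 20)
  subjects <- rep(1:10, each = 10)
  folds <- stratified_kfold(labels, k = 5, seed = 3, subject_aware = TRUE,
                            subject_ids = subjects)
  for (f in folds) {
    s_test <- unique(subjects[f$test_idx])
    s_train <- unique(subjects[f$train_idx])
    expect_length(intersect(s_test, s_train), 0L)
  }
})

test_that("zero learning rate leaves the model unchanged after an epoch", {
  ds <- tiny_cohort()
  net <- build_model(tiny_config(), seed = 20)
  before <- net$params
  tc <- train_config(lr = 0, weight_decay = 0, epochs = 1, batch_size = 32,
                     val_fraction = 0, seed = 1)
  train_model(net, ds, train_idx = 1:64, val_idx = integer(), config = tc)
  expect_identical(net$params, before)
})

test_that("cross-validation with stub classifiers gives closed-form metrics", {
  labels <- c(rep(0L, 60), rep(1L, 10), rep(2L, 10), rep(3L, 10), rep(4L, 10))
  set.seed(30)
  labels <- sample(labels)
  ds <- list(labels = labels, subject_ids = rep(1L, 100))
  class(ds) <- "epoch_dataset"
  # a perfect classifier
  perfect <- function(dataset, train_idx, val_idx, fold_id) {
    function(test_idx) dataset$labels[test_idx]
  }
  cv <- cross_validate(ds, train_cfg = train_config(seed = 4), trainer = perfect)
  expect_length(cv$per_fold, 5L)
  for (r in cv$per_fold) {
    expect_equal(r$OA, 100)
    expect_equal(r$kappa, 1)
    expect_equal(r$MF1, 1)
  }
  expect_equal(cv$summary$sd, rep(0, 3), tolerance = 1e-12)
  # majority-class stub on a 60/10/10/10/10 mixture: OA 60%, kappa 0
  majority <- function(dataset, train_idx, val_idx, fold_id) {
    function(test_idx) rep(0L, length(test_idx))
  }
  cv2 <- cross_validate(ds, train_cfg = train_config(seed = 4), trainer = majority)
  oa <- cv2$summary$mean[cv2$summary$metric == "OA"]
  kp <- cv2$summary$mean[cv2$summary$metric == "kappa"]
  expect_equal(oa, 60, tolerance = 1e-9)
  expect_equal(kp, 0, tolerance = 1e-9)
})

test_that("checkpoint selection is the earliest argmax of validation accuracy", {
  ds <- tiny_cohort()
  net <- build_model(tiny_config(), seed = 21)
  tc <- train_config(lr = 1e-3, epochs = 3, batch_size = 32,
                     val_fraction = 0, seed = 2)
  res <- train_model(net, ds, train_idx = 1:64, val_idx = 65:80, config = tc)
  expect_equal(nrow(res$history), 3L)
  acc <- res$history$val_acc
  expect_identical(res$best_epoch, which(acc == max(acc))[1L])
  # the restored network reproduces the checkpointed validation accuracy
  pred <- model_predict(net, ds, 65:80)
  expect_equal(mean(pred$labels == ds$labels[65:80]), max(acc))
})

test_that("training configuration validates and the grid is the stated 3x3", {
  g <- hyperparameter_grid()
  expect_equal(nrow(g), 9L)
  expect_setequal(unique(g$lr), c(1e-3, 1e-4, 1e-5))
  expect_setequal(unique(g$weight_decay), c(1e-5, 1e-4, 1e-3))
  expect_error(train_config(lr = -1), "lr")
})
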