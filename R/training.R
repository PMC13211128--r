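# Training protocol: Adam with L2 weight decay, shuffled mini-batches,
# per-epoch validation, best-validation-accuracy checkpointing (ties ->
# earliest epoch), and stratified epoch-level k-fold cross-validation.

#' Training configuration
#'
#' Defaults follow the standard protocol: Adam, learning rate 1e-4, weight
#' decay 1e-4, 100 epochs, batch size 32. The companion hyper-parameter grid
#' is the 3x3 cross of lr in {1e-3, 1e-4, 1e-5} and weight decay in
#' {1e-5, 1e-4, 1e-3} (see [hyperparameter_grid()]). Validation data for
#' checkpoint selection is split off the training fold (stratified,
#' `val_fraction`).
#'
#' @param lr learning rate (>= 0; 0 is the documented null-update case).
#' @param weight_decay L2 coefficient added to the gradient.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param val_fraction fraction of the training fold held out for
#'   checkpoint selection.
#' @param seed seed controlling shuffling and the validation split.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, epochs = 100L,
                         batch_size = 32L, val_fraction = 0.1, seed = 1L) {
  stopifnot(lr >= 0, weight_decay >= 0, epochs >= 1, batch_size >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(lr = lr, weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' The stated 3x3 hyper-parameter grid
#' @return data.frame with columns `lr` and `weight_decay`.
#' @export
hyperparameter_grid <- function() {
  expand.grid(lr = c(1e-3, 1e-4, 1e-5), weight_decay = c(1e-5, 1e-4, 1e-3))
}

#' Stratified k-fold splits at the epoch level
#'
#' Partitions epochs into k folds of equal size (within one) preserving
#' per-class proportions (within one sample). With `subject_aware = TRUE`
#' the folds partition subjects instead, for leakage-free evaluation.
#'
#' @param labels integer stage labels.
#' @param k number of folds.
#' @param seed shuffling seed.
#' @param subject_aware partition subjects rather than epochs.
#' @param subject_ids required when `subject_aware`.
#' @return list of fold splits, each with `fold_id`, `train_idx`,
#'   `test_idx`, `stratified`, `subject_aware`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L,
                             subject_aware = FALSE, subject_ids = NULL) {
  n <- length(labels)
  fold_of <- integer(n)
  if (subject_aware) {
    if (is.null(subject_ids)) stopf("subject_aware splits need subject_ids")
    subs <- unique(subject_ids)
    if (length(subs) < k) stopf("only %d subjects for %d folds", length(subs), k)
    subs <- with_seed(seed, sample(subs))
    sf <- ((seq_along(subs) - 1L) %% k) + 1L
    for (i in seq_along(subs)) fold_of[subject_ids == subs[i]] <- sf[i]
  } else {
    tab <- table(labels)
    small <- names(tab)[tab < k]
    if (length(small)) {
      stopf("class(es) %s have fewer than k = %d members",
            paste(stage_name(as.integer(small)), collapse = ", "), k)
    }
    start <- 0L
    with_seed(seed, {
      for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        fold_of[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
        start <- (start + length(idx)) %% k
      }
    })
  }
  lapply(seq_len(k), function(f) {
    list(fold_id = f,
         train_idx = which(fold_of != f),
         test_idx = which(fold_of == f),
         stratified = !subject_aware,
         subject_aware = subject_aware)
  })
}

# Stratified validation carve-out from a training index set.
split_validation <- function(labels, train_idx, fraction, seed) {
  if (fraction <= 0) return(list(train = train_idx, val = integer()))
  val <- integer()
  with_seed(seed, {
    for (cl in unique(labels[train_idx])) {
      idx <- train_idx[labels[train_idx] == cl]
      nv <- max(1L, round(fraction * length(idx)))
      val <- c(val, sample(idx, min(nv, length(idx))))
    }
  })
  list(train = setdiff(train_idx, val), val = sort(val))
}

#' Train a model
#'
#' Cross-entropy training with Adam. The sample order is reshuffled every
#' epoch; validation accuracy is measured after each epoch, and the
#' checkpoint with the best validation accuracy is retained (ties broken
#' toward the earliest epoch). Aborts with diagnostics if the loss becomes
#' non-finite. A trailing mini-batch of size one is dropped (batch
#' statistics are undefined for it).
#'
#' @param net a [build_model()] network; updated in place and left at the
#'   best checkpoint.
#' @param dataset a labeled, rate-harmonized [epoch_dataset()].
#' @param train_idx,val_idx epoch index sets. When `val_idx` is `NULL` a
#'   stratified `val_fraction` carve-out of `train_idx` is used.
#' @param config a [train_config()].
#' @return list with `checkpoint` (best state), `history` (per-epoch train
#'   loss, train accuracy and validation accuracy), `best_epoch`.
#' @export
train_model <- function(net, dataset, train_idx = NULL, val_idx = NULL,
                        config = train_config()) {
  stopifnot(inherits(net, "fusion_net"), inherits(config, "train_config"))
  labels <- dataset$labels
  if (is.null(labels)) stopf("training requires a labeled dataset")
  train_idx <- train_idx %||% seq_len(n_epochs(dataset))
  if (is.null(val_idx)) {
    sv <- split_validation(labels, train_idx, config$val_fraction,
                           derive_seed(config$seed, 7L))
    train_idx <- sv$train
    val_idx <- sv$val
  }
  use_eeg <- net$config$use_eeg
  use_eog <- net$config$use_eog
  opt <- adam_init()
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, epoch = NA_integer_, ckpt = NULL)
  for (ep in seq_len(config$epochs)) {
    order_ep <- with_seed(derive_seed(config$seed, 11L, ep), sample(train_idx))
    losses <- numeric()
    correct <- 0L
    seen <- 0L
    pos <- 1L
    while (pos <= length(order_ep)) {
      take <- order_ep[pos:min(pos + config$batch_size - 1L, length(order_ep))]
      pos <- pos + length(take)
      if (length(take) < 2L && length(order_ep) >= 2L) next  # skip size-1 tail
      b <- dataset_batch(dataset, take)
      out <- model_forward(net, eeg = if (use_eeg) b$eeg else NULL,
                           eog = if (use_eog) b$eog else NULL, train = TRUE)
      ce <- cross_entropy(out$logits, b$labels)
      if (!is.finite(ce$loss)) {
        stopf("non-finite loss at epoch %d (batch starting %d): lr=%g, wd=%g",
              ep, take[1L], config$lr, config$weight_decay)
      }
      losses <- c(losses, ce$loss)
      correct <- correct + sum(max.col(t(ce$probs)) - 1L == b$labels)
      seen <- seen + length(take)
      model_backward(net, out$ctx, ce$dlogits)
      st <- adam_step(net$params, net$grads, opt, lr = config$lr,
                      weight_decay = config$weight_decay)
      net$params <- st$params
      opt <- st$state
    }
    val_acc <- if (length(val_idx)) {
      pred <- model_predict(net, dataset, val_idx, batch_size = config$batch_size)
      mean(pred$labels == labels[val_idx])
    } else NA_real_
    history <- rbind(history, data.frame(epoch = ep, train_loss = mean(losses),
                                         train_acc = correct / max(seen, 1L),
                                         val_acc = val_acc))
    score <- if (is.na(val_acc)) correct / max(seen, 1L) else val_acc
    if (score > best$acc) {        # strict: ties keep the earliest epoch
      best <- list(acc = score, epoch = ep, ckpt = model_checkpoint(net))
    }
  }
  model_restore(net, best$ckpt)
  list(checkpoint = best$ckpt, history = history, best_epoch = best$epoch)
}

summarize_reports <- function(reports) {
  vals <- data.frame(OA = vapply(reports, `[[`, 0, "OA"),
                     kappa = vapply(reports, `[[`, 0, "kappa"),
                     MF1 = vapply(reports, `[[`, 0, "MF1"))
  data.frame(metric = names(vals),
             mean = vapply(vals, mean, 0),
             sd = vapply(vals, stats::sd, 0),
             row.names = NULL)
}

#' Stratified cross-validation
#'
#' Epoch-level stratified k-fold evaluation. Each fold trains on the other
#' folds (with a stratified validation carve-out for checkpointing) and is
#' scored on the held-out fold; the summary reports mean and standard
#' deviation of OA, kappa and MF1 across folds.
#'
#' A custom `trainer` can replace the network entirely (used for stub
#' classifiers in tests): a function
#' `function(dataset, train_idx, val_idx, fold_id)` returning a predictor
#' `function(test_idx) -> integer labels`.
#'
#' @param dataset labeled [epoch_dataset()].
#' @param model_cfg a [model_config()] (ignored when `trainer` is given).
#' @param train_cfg a [train_config()].
#' @param k folds.
#' @param trainer optional custom trainer (see details).
#' @param subject_aware partition subjects instead of epochs.
#' @return list with `per_fold` ([metrics_report()] per fold), `summary`
#'   (mean +/- sd table), `folds`, `histories`.
#' @export
cross_validate <- function(dataset, model_cfg = NULL, train_cfg = train_config(),
                           k = 5L, trainer = NULL, subject_aware = FALSE) {
  labels <- dataset$labels
  folds <- stratified_kfold(labels, k = k, seed = train_cfg$seed,
                            subject_aware = subject_aware,
                            subject_ids = dataset$subject_ids)
  trainer <- trainer %||% function(ds, train_idx, val_idx, fold_id) {
    net <- build_model(model_cfg, seed = derive_seed(train_cfg$seed, 23L, fold_id))
    cfg_f <- train_cfg
    cfg_f$seed <- derive_seed(train_cfg$seed, 29L, fold_id)
    train_model(net, ds, train_idx, val_idx, cfg_f)
    function(test_idx) model_predict(net, ds, test_idx)$labels
  }
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    sv <- split_validation(labels, folds[[f]]$train_idx, train_cfg$val_fraction,
                           derive_seed(train_cfg$seed, 31L, f))
    predict_fun <- trainer(dataset, sv$train, sv$val, f)
    pred <- predict_fun(folds[[f]]$test_idx)
    reports[[f]] <- metrics_report(labels[folds[[f]]$test_idx], pred)
  }
  list(per_fold = reports, summary = summarize_reports(reports), folds = folds)
}

#' Component ablation harness
#'
#' Trains the five standard variants (EEG only, EOG only, concatenation,
#' + fusion, full network) on a shared stratified train/test split per seed
#' and reports test OA/kappa per method and seed. Scaled for property
#' checks (ordering across methods), not absolute performance.
#'
#' @param dataset labeled, harmonized [epoch_dataset()].
#' @param train_cfg a [train_config()].
#' @param config_args list of arguments passed to [ablation_config()]
#'   (channel counts, width multiplier, ...).
#' @param methods subset of 1:5.
#' @param seeds integer vector; one split + training per seed.
#' @param test_fraction held-out fraction per seed.
#' @return data.frame with columns method, seed, OA, kappa, MF1.
#' @export
run_ablation <- function(dataset, train_cfg, config_args = list(),
                         methods = 1:5, seeds = 1L, test_fraction = 0.25) {
  labels <- dataset$labels
  out <- NULL
  for (sd in seeds) {
    sp <- split_validation(labels, seq_len(n_epochs(dataset)), test_fraction,
                           derive_seed(sd, 41L))
    train_idx <- sp$train
    test_idx <- sp$val
    for (m in methods) {
      cfg <- do.call(ablation_config, c(list(method = m), config_args))
      net <- build_model(cfg, seed = derive_seed(sd, 43L, m))
      tc <- train_cfg
      tc$seed <- derive_seed(sd, 47L, m)
      train_model(net, dataset, train_idx, NULL, tc)
      rep <- metrics_report(labels[test_idx],
                            model_predict(net, dataset, test_idx)$labels)
      out <- rbind(out, data.frame(method = m, seed = sd, OA = rep$OA,
                                   kappa = rep$kappa, MF1 = rep$MF1))
    }
  }
  out
}
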