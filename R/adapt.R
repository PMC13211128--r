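# Subject-adaptive external validation: per-subject stratified 1:9 split,
# head-only fine-tuning with the feature extractor frozen (checksum-verified,
# not trusted), and before/after reporting per subject.

#' Head fine-tuning budget
#'
#' Adaptation updates only the classification head on a handful of labeled
#' epochs. The default budget (50 full-batch epochs at learning rate 1e-3,
#' a grid value) is sized for adaptation sets of tens of samples; see the
#' methods vignette for the rationale.
#'
#' @param epochs fine-tuning epochs over the adaptation set.
#' @param lr learning rate.
#' @param weight_decay L2 coefficient.
#' @param batch_size mini-batch size (adaptation sets are usually smaller,
#'   giving full-batch steps).
#' @return object of class `adapt_config`.
#' @export
adapt_config <- function(epochs = 50L, lr = 1e-3, weight_decay = 1e-4,
                         batch_size = 32L) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size)),
            class = "adapt_config")
}

#' Stratified per-subject adaptation split
#'
#' Splits one subject's epochs into an adaptation set (~`ratio`) and a test
#' set, stratified by stage with largest-remainder rounding; every class
#' with at least two epochs contributes at least one adaptation epoch where
#' possible. Degenerate subjects (single class, very few epochs) produce a
#' warning and a best-effort split.
#'
#' @param labels the subject's stage labels.
#' @param ratio adaptation fraction (default 0.10, i.e. a 1:9 split).
#' @param seed shuffling seed.
#' @return list with `adapt_idx` and `test_idx` (disjoint, exhaustive,
#'   indices into `labels`).
#' @export
subject_split <- function(labels, ratio = 0.1, seed = 1L) {
  n <- length(labels)
  if (n < 2L) {
    warnf("subject has %d epoch(s); best-effort split", n)
    return(list(adapt_idx = integer(), test_idx = seq_len(n)))
  }
  classes <- sort(unique(labels))
  n_c <- vapply(classes, function(cl) sum(labels == cl), 0L)
  target <- round(ratio * n)
  quota <- floor(ratio * n_c)
  frac <- ratio * n_c - quota
  extra <- target - sum(quota)
  if (extra > 0) {
    ord <- order(frac, decreasing = TRUE)
    quota[ord[seq_len(min(extra, length(ord)))]] <-
      quota[ord[seq_len(min(extra, length(ord)))]] + 1L
  }
  bump <- quota == 0L & n_c >= 2L
  quota[bump] <- 1L
  quota <- pmin(quota, n_c - 1L)   # never swallow a whole class
  quota[quota < 0L] <- 0L
  if (length(classes) == 1L && n < 10L) warnf("single-class subject with %d epochs", n)
  adapt <- integer()
  with_seed(seed, {
    for (i in seq_along(classes)) {
      idx <- which(labels == classes[i])
      if (quota[i] > 0L) adapt <- c(adapt, sample(idx, quota[i]))
    }
  })
  list(adapt_idx = sort(adapt), test_idx = setdiff(seq_len(n), adapt))
}

backbone_digest <- function(net) {
  params_digest(net$params[!startsWith(names(net$params), "head.")])
}

clone_net <- function(net) {
  net2 <- build_model(net$config, seed = net$seed)
  model_restore(net2, model_checkpoint(net))
  net2
}

#' Head-only fine-tuning
#'
#' Adapts the classification head to one subject while keeping every
#' feature-extraction parameter (and all batch-norm running statistics)
#' frozen. Because the backbone is fixed, the time-pooled features of the
#' adaptation epochs are computed once and the head is trained on the cached
#' vectors. The freeze contract is verified by digesting the backbone
#' parameters before and after.
#'
#' @param net a trained `fusion_net`; not modified (a copy is adapted).
#' @param dataset the subject's [epoch_dataset()].
#' @param adapt_idx adaptation epoch indices (non-empty).
#' @param config an [adapt_config()].
#' @return list: `net` (adapted copy), `digest_before`, `digest_after`
#'   (backbone checksums; equal by construction, asserted), and
#'   `head_params_updated`.
#' @export
finetune_head <- function(net, dataset, adapt_idx, config = adapt_config()) {
  if (!length(adapt_idx)) stopf("empty adaptation set")
  labels <- dataset$labels[adapt_idx]
  net2 <- clone_net(net)
  d_before <- backbone_digest(net2)
  X <- t(head_features(net2, dataset, adapt_idx))   # (fused_dim, n)
  W <- net2$params[["head.fc.W"]]
  b <- net2$params[["head.fc.b"]]
  opt <- adam_init()
  n <- length(adapt_idx)
  for (e in seq_len(config$epochs)) {
    pos <- 1L
    while (pos <= n) {
      take <- pos:min(pos + config$batch_size - 1L, n)
      pos <- pos + length(take)
      ce <- cross_entropy(W %*% X[, take, drop = FALSE] + b, labels[take])
      gW <- tcrossprod(ce$dlogits, X[, take, drop = FALSE])
      gb <- rowSums(ce$dlogits)
      st <- adam_step(list(W = W, b = b), list(W = gW, b = gb), opt,
                      lr = config$lr, weight_decay = config$weight_decay)
      W <- st$params$W
      b <- st$params$b
      opt <- st$state
    }
  }
  net2$params[["head.fc.W"]] <- W
  net2$params[["head.fc.b"]] <- b
  d_after <- backbone_digest(net2)
  stopifnot(identical(d_before, d_after))
  list(net = net2, digest_before = d_before, digest_after = d_after,
       head_params_updated = length(W) + length(b))
}

# Time-pooled pre-head features (the classification head's input).
head_features <- function(net, dataset, idx, batch_size = 32L) {
  feats <- NULL
  pos <- 1L
  use_eeg <- net$config$use_eeg
  use_eog <- net$config$use_eog
  while (pos <= length(idx)) {
    take <- idx[pos:min(pos + batch_size - 1L, length(idx))]
    b <- dataset_batch(dataset, take)
    out <- model_forward(net, eeg = if (use_eeg) b$eeg else NULL,
                         eog = if (use_eog) b$eog else NULL, train = FALSE)
    feats <- rbind(feats, t(gap_time_forward(out$ctx$v$Fout)$out))
    pos <- pos + length(take)
  }
  feats
}

#' Subject-adaptive external validation
#'
#' Applies a trained model to held-out subjects: first direct transfer
#' (no adaptation), then — when `with_adaptation` — a stratified 1:9 split
#' per subject, head-only fine-tuning on the 10% adaptation set, and
#' re-evaluation on the 90% test set. Direct-transfer accuracy is measured
#' on the same test epochs so before/after are comparable; adaptation never
#' touches test epochs (the index sets are returned for audit).
#'
#' @param net trained `fusion_net`.
#' @param dataset held-out subjects' [epoch_dataset()].
#' @param train_subjects subject ids seen in training; overlap is an error.
#' @param with_adaptation run the fine-tuning arm.
#' @param ratio adaptation fraction.
#' @param seed split seed.
#' @param config an [adapt_config()].
#' @return data.frame, one row per subject: OA_before, OA_after (NA without
#'   adaptation), n_adapt, n_test, head_params_updated, backbone_unchanged;
#'   the per-subject index sets are attached as the `splits` attribute.
#' @export
external_validate <- function(net, dataset, train_subjects = NULL,
                              with_adaptation = TRUE, ratio = 0.1, seed = 1L,
                              config = adapt_config()) {
  subs <- unique(dataset$subject_ids)
  if (!is.null(train_subjects) && length(intersect(subs, train_subjects))) {
    stopf("held-out subjects overlap training subjects: %s",
          paste(intersect(subs, train_subjects), collapse = ", "))
  }
  rows <- NULL
  splits <- list()
  for (s in subs) {
    idx <- which(dataset$subject_ids == s)
    labs <- dataset$labels[idx]
    sp <- subject_split(labs, ratio = ratio, seed = derive_seed(seed, 61L, match(s, subs)))
    test_idx <- idx[sp$test_idx]
    adapt_idx <- idx[sp$adapt_idx]
    splits[[as.character(s)]] <- list(adapt = adapt_idx, test = test_idx)
    oa_before <- metrics_report(dataset$labels[test_idx],
                                model_predict(net, dataset, test_idx)$labels)$OA
    oa_after <- NA_real_
    n_head <- NA_integer_
    unchanged <- NA
    if (with_adaptation && length(adapt_idx)) {
      ft <- finetune_head(net, dataset, adapt_idx, config)
      oa_after <- metrics_report(dataset$labels[test_idx],
                                 model_predict(ft$net, dataset, test_idx)$labels)$OA
      n_head <- ft$head_params_updated
      unchanged <- identical(ft$digest_before, ft$digest_after)
    }
    rows <- rbind(rows, data.frame(subject_id = s, OA_before = oa_before,
                                   OA_after = oa_after,
                                   n_adapt = length(adapt_idx),
                                   n_test = length(test_idx),
                                   head_params_updated = n_head,
                                   backbone_unchanged = unchanged))
  }
  attr(rows, "splits") <- splits
  rows
}
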