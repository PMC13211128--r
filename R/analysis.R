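# Stage-wise EEG-EOG association statistics, branch probes around the
# fusion interaction, and Grad-CAM saliency for 1-D signals.

#' Spearman rank correlation of one epoch pair
#'
#' Pearson correlation of average-tie ranks, computed directly (the test
#' suite cross-checks against the generic correlation routine).
#'
#' @param x,y equal-length numeric vectors (one EEG and one EOG channel of a
#'   harmonized epoch).
#' @return rho in `[-1, 1]`, or `NA` when either input is constant
#'   (undefined ranks).
#' @export
spearman_epoch <- function(x, y) {
  if (length(x) != length(y)) stopf("inputs differ in length (%d vs %d)", length(x), length(y))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sx <- sqrt(sum((rx - mean(rx))^2))
  sy <- sqrt(sum((ry - mean(ry))^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / (sx * sy)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based one-way test across groups, with the standard tie correction;
#' the p-value uses the chi-square approximation with k - 1 degrees of
#' freedom.
#'
#' @param groups list of numeric vectors (at least two non-empty).
#' @return list with the statistic `H`, `p`, and `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- Filter(length, groups)
  k <- length(groups)
  if (k < 2L) stopf("need at least two non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (length(unique(x)) == 1L) return(list(H = 0, p = 1, df = k - 1L))
  r <- rank(x, ties.method = "average")
  sizes <- lengths(groups)
  idx <- rep(seq_len(k), sizes)
  rbar <- tapply(r, idx, mean)
  H <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / corr
  list(H = H, p = stats::pchisq(H, df = k - 1L, lower.tail = FALSE), df = k - 1L)
}

#' Stage-wise EEG-EOG correlation analysis
#'
#' Computes a per-epoch Spearman rho between the (preprocessed, harmonized)
#' EEG and EOG signals, groups the values by stage, and runs a
#' Kruskal-Wallis omnibus test across stages. With multichannel modalities
#' the default policy averages rho over all EEG x EOG channel pairs per
#' epoch; `"first_pair"` uses only channel 1 of each modality.
#'
#' @param dataset labeled [epoch_dataset()] with equal modality rates.
#' @param channel_policy `"mean_pairs"` or `"first_pair"`.
#' @return object of class `stage_correlation_result`: per-stage rho
#'   vectors, medians, medians of `|rho|`, and the omnibus `H` / `p`.
#' @export
stagewise_correlation <- function(dataset, channel_policy = c("mean_pairs", "first_pair")) {
  channel_policy <- match.arg(channel_policy)
  stopifnot(inherits(dataset, "epoch_dataset"))
  if (is.null(dataset$eog)) stopf("correlation analysis needs both modalities")
  if (abs(dataset$fs_eeg - dataset$fs_eog) > 1e-12) {
    stopf("modalities at different rates (%g vs %g Hz); harmonize first",
          dataset$fs_eeg, dataset$fs_eog)
  }
  if (is.null(dataset$labels)) stopf("labeled dataset required")
  n <- n_epochs(dataset)
  ce <- dim(dataset$eeg)[2L]
  co <- dim(dataset$eog)[2L]
  pairs <- if (channel_policy == "first_pair") {
    matrix(c(1L, 1L), 1L)
  } else as.matrix(expand.grid(seq_len(ce), seq_len(co)))
  rho <- numeric(n)
  for (i in seq_len(n)) {
    vals <- apply(pairs, 1L, function(pr) {
      spearman_epoch(dataset$eeg[i, pr[1L], ], dataset$eog[i, pr[2L], ])
    })
    rho[i] <- mean(vals, na.rm = TRUE)
  }
  groups <- list()
  for (s in 0:4) {
    v <- rho[dataset$labels == s & !is.na(rho)]
    if (!length(v)) {
      warnf("stage %s has no epochs; omitted from the correlation result", stage_name(s))
      next
    }
    groups[[stage_name(s)]] <- v
  }
  kw <- kruskal_wallis(groups)
  structure(list(rho_by_stage = groups,
                 medians = vapply(groups, stats::median, 0),
                 medians_abs = vapply(groups, function(v) stats::median(abs(v)), 0),
                 H = kw$H, p = kw$p, policy = channel_policy),
            class = "stage_correlation_result")
}

#' @export
print.stage_correlation_result <- function(x, ...) {
  cat("Per-stage median rho (|rho|):\n")
  for (nm in names(x$medians)) {
    cat(sprintf("  %-4s %+.4f (%.4f)  n=%d\n", nm, x$medians[[nm]],
                x$medians_abs[[nm]], length(x$rho_by_stage[[nm]])))
  }
  cat(sprintf("Kruskal-Wallis H = %.2f, p = %.3g\n", x$H, x$p))
  invisible(x)
}

# ---- linear probe ----------------------------------------------------------
# Multinomial logistic probe on frozen features (full-batch gradient
# descent with Adam; the objective is convex so zero init is canonical).
probe_train <- function(X, y, n_classes = 5L, epochs = 300L, lr = 0.05) {
  D <- nrow(X)
  W <- matrix(0, n_classes, D)
  b <- numeric(n_classes)
  opt <- adam_init()
  for (e in seq_len(epochs)) {
    logits <- W %*% X + b
    ce <- cross_entropy(logits, y)
    dW <- tcrossprod(ce$dlogits, X)
    db <- rowSums(ce$dlogits)
    st <- adam_step(list(W = W, b = b), list(W = dW, b = db), opt, lr = lr)
    W <- st$params$W
    b <- st$params$b
    opt <- st$state
  }
  list(W = W, b = b,
       predict = function(Xn) max.col(t(W %*% Xn + b)) - 1L)
}

# Time-pooled branch features from a trained network: (N, embed_dim).
branch_features <- function(net, dataset, idx, which, batch_size = 32L) {
  feats <- NULL
  pos <- 1L
  while (pos <= length(idx)) {
    take <- idx[pos:min(pos + batch_size - 1L, length(idx))]
    b <- dataset_batch(dataset, take)
    out <- model_forward(net, eeg = b$eeg, eog = b$eog, train = FALSE,
                         keep_intermediates = TRUE)
    fm <- out$intermediates[[which]]
    if (is.null(fm)) stopf("intermediate '%s' not available for this config", which)
    feats <- rbind(feats, t(gap_time_forward(fm)$out))
    pos <- pos + length(take)
  }
  feats
}

#' Branch performance before / after cross-modal interaction
#'
#' Quantifies what each modality branch alone can do around the fusion
#' point. `"before"` trains the two single-modality pipelines (ablation
#' methods 1 and 2) from scratch. `"after"` freezes a trained full network,
#' extracts the time-pooled modulated branch features (each branch rescaled
#' by the gate computed from the other modality) and fits a linear softmax
#' probe on them — measuring the information content of each branch after
#' the interaction without retraining the backbones.
#'
#' @param net a trained full `fusion_net` (required for `"after"`).
#' @param dataset labeled harmonized [epoch_dataset()].
#' @param mode `"before"`, `"after"` or both.
#' @param train_idx,test_idx index sets (probe / single-branch training vs
#'   evaluation).
#' @param train_cfg a [train_config()] for the `"before"` pipelines.
#' @param config_args arguments for [ablation_config()] in `"before"` mode.
#' @return data.frame with branch, mode, OA and kappa rows.
#' @export
branch_probe <- function(net = NULL, dataset, mode = c("before", "after"),
                         train_idx, test_idx, train_cfg = train_config(),
                         config_args = list()) {
  mode <- match.arg(mode, several.ok = TRUE)
  labels <- dataset$labels
  out <- NULL
  if ("before" %in% mode) {
    for (m in 1:2) {
      cfg <- do.call(ablation_config, c(list(method = m), config_args))
      bn <- build_model(cfg, seed = derive_seed(train_cfg$seed, 53L, m))
      tc <- train_cfg
      tc$seed <- derive_seed(train_cfg$seed, 59L, m)
      train_model(bn, dataset, train_idx, NULL, tc)
      rep <- metrics_report(labels[test_idx], model_predict(bn, dataset, test_idx)$labels)
      out <- rbind(out, data.frame(branch = c("EEG", "EOG")[m], mode = "before",
                                   OA = rep$OA, kappa = rep$kappa))
    }
  }
  if ("after" %in% mode) {
    if (is.null(net)) stopf("'after' mode needs a trained full model")
    if (!net$config$use_fusion) stopf("'after' mode needs a model with the fusion module")
    for (br in c("fbar_eeg", "fbar_eog")) {
      Xtr <- t(branch_features(net, dataset, train_idx, br))
      Xte <- t(branch_features(net, dataset, test_idx, br))
      pr <- probe_train(Xtr, labels[train_idx])
      rep <- metrics_report(labels[test_idx], pr$predict(Xte))
      out <- rbind(out, data.frame(branch = if (br == "fbar_eeg") "EEG" else "EOG",
                                   mode = "after", OA = rep$OA, kappa = rep$kappa))
    }
  }
  out
}

#' Grad-CAM saliency for one epoch
#'
#' Gradient-weighted class activation mapping at one of three tap points:
#' the EEG branch embedding, the EOG branch embedding, or the output of the
#' gated temporal-channel attention block. Channel weights are the
#' time-averaged gradients of the target-class logit; the map is the
#' ReLU-ed weighted sum of activations, linearly upsampled to the input
#' length and normalized to `[0, 1]` (an all-zero map is returned as zeros
#' and flagged).
#'
#' @param net an eval-mode `fusion_net`.
#' @param eeg,eog single-epoch inputs, `(C, L)` matrices (as from
#'   [generate_epoch()] or a dataset row).
#' @param tap `"eeg_branch"`, `"eog_branch"` or `"gated_output"`.
#' @param target_class stage name or code whose logit is explained.
#' @return object of class `gradcam_map`: `values` (feature resolution),
#'   `upsampled` (input resolution), `tap`, `target_class`, `flagged_zero`.
#' @export
gradcam <- function(net, eeg = NULL, eog = NULL,
                    tap = c("gated_output", "eeg_branch", "eog_branch"),
                    target_class = "N2") {
  tap <- match.arg(tap)
  if (is.character(target_class)) target_class <- stage_code(target_class)
  as_batch <- function(m) if (is.null(m)) NULL else array(m, c(dim(m), 1L))
  L <- if (!is.null(eeg)) ncol(eeg) else ncol(eog)
  out <- model_forward(net, eeg = as_batch(eeg), eog = as_batch(eog),
                       train = FALSE, keep_intermediates = TRUE)
  K <- net$config$n_classes
  d <- matrix(0, K, 1L)
  d[target_class + 1L, 1L] <- 1
  taps <- model_backward(net, out$ctx, d, tap_grads = TRUE)
  key <- switch(tap, eeg_branch = "eeg_embed", eog_branch = "eog_embed",
                gated_output = "gtca_out")
  akey <- switch(tap, eeg_branch = "f_eeg", eog_branch = "f_eog", gated_output = "F")
  grad <- taps[[key]]
  act <- out$intermediates[[akey]]
  if (is.null(grad) || is.null(act)) stopf("tap '%s' not available for this config", tap)
  g2 <- matrix(grad[, , 1L], nrow = dim(grad)[1L])
  a2 <- matrix(act[, , 1L], nrow = dim(act)[1L])
  w <- rowMeans(g2)                       # time-averaged gradient per channel
  map <- pmax(colSums(a2 * w), 0)
  flagged <- max(map) == 0
  if (!flagged) map_n <- map / max(map) else map_n <- map
  up <- stats::approx(seq_along(map_n), map_n, n = L)$y
  structure(list(values = map_n, upsampled = up, tap = tap,
                 target_class = target_class, flagged_zero = flagged),
            class = "gradcam_map")
}
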