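# Confusion-matrix evaluation. Overall accuracy is the proportion of
# correctly predicted samples (trace / N); chance agreement for Cohen's
# kappa is the standard multiclass marginal product, which reduces to the
# per-class binary form at two classes. Macro-F1 averages per-class F1
# without weighting; a class absent from both truth and prediction
# contributes F1 = 0 with a warning (conservative on small folds).

#' Confusion matrix
#'
#' @param y_true,y_pred integer stage labels 0..4 (rows = true,
#'   columns = predicted; order W, N1, N2, N3, REM).
#' @param n_classes number of classes.
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, n_classes = 5L) {
  if (length(y_true) != length(y_pred)) stopf("label vectors differ in length")
  if (!all(y_true %in% 0:(n_classes - 1L)) || !all(y_pred %in% 0:(n_classes - 1L))) {
    stopf("labels out of range 0..%d", n_classes - 1L)
  }
  cm <- table(factor(y_true, levels = 0:(n_classes - 1L)),
              factor(y_pred, levels = 0:(n_classes - 1L)))
  cm <- matrix(as.integer(cm), n_classes, n_classes)
  nm <- if (n_classes == 5L) STAGES else as.character(0:(n_classes - 1L))
  dimnames(cm) <- list(true = nm, pred = nm)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Overall accuracy in percent
#'
#' `100 * trace / N`: the proportion of correctly predicted samples.
#'
#' @param cm a [confusion()] matrix.
#' @return percentage in `[0, 100]`.
#' @export
overall_accuracy <- function(cm) {
  n <- sum(cm)
  if (n == 0) stopf("empty confusion matrix")
  100 * sum(diag(cm)) / n
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(P0 - Pe) / (1 - Pe)` with `P0 = trace / N`
#' and the multiclass expected agreement
#' `Pe = sum_c (row_c / N) (col_c / N)`.
#'
#' @param cm a [confusion()] matrix.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  n <- sum(cm)
  if (n == 0) stopf("empty confusion matrix")
  p0 <- sum(diag(cm)) / n
  pe <- sum((rowSums(cm) / n) * (colSums(cm) / n))
  if (abs(1 - pe) < 1e-15) {
    if (abs(1 - p0) < 1e-15) return(1)
    stopf("kappa undefined: degenerate identical marginals with imperfect agreement")
  }
  (p0 - pe) / (1 - pe)
}

per_class_prf <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm)) - 1L),
             precision = precision, recall = recall, f1 = f1,
             support = rowSums(cm), row.names = NULL)
}

#' Macro-F1
#'
#' Unweighted mean of per-class F1 scores. Classes with no true and no
#' predicted samples get F1 = 0 (with a warning), which depresses the score
#' on folds missing a stage.
#'
#' @param cm a [confusion()] matrix.
#' @return macro-F1 in `[0, 1]`.
#' @export
macro_f1 <- function(cm) {
  pc <- per_class_prf(cm)
  absent <- rowSums(cm) + colSums(cm) == 0
  if (any(absent)) {
    warnf("class(es) %s absent from truth and prediction; F1 = 0 contributed",
          paste(rownames(cm)[absent], collapse = ", "))
  }
  mean(pc$f1)
}

#' Full metrics report
#'
#' @param y_true,y_pred label vectors, or pass `cm` directly.
#' @param cm optional precomputed [confusion()] matrix.
#' @return object of class `metrics_report`: OA (percent), kappa, MF1
#'   (fraction), the per-class precision/recall/F1 table and the matrix.
#' @export
metrics_report <- function(y_true = NULL, y_pred = NULL, cm = NULL) {
  if (is.null(cm)) cm <- confusion(y_true, y_pred)
  structure(list(OA = overall_accuracy(cm),
                 kappa = cohens_kappa(cm),
                 MF1 = suppressWarnings(macro_f1(cm)),
                 per_class = per_class_prf(cm),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("OA %.2f%%  kappa %.4f  MF1 %.4f\n", x$OA, x$kappa, x$MF1))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Confusion matrix as row percentages
#'
#' The rendering used in stage-wise heat tables: each row (true stage)
#' normalized to percent.
#'
#' @param cm a [confusion()] matrix.
#' @return numeric matrix of row percentages.
#' @export
confusion_percent <- function(cm) {
  rs <- rowSums(cm)
  out <- 100 * sweep(unclass(cm), 1L, pmax(rs, 1L), "/")
  out[rs == 0, ] <- NA_real_
  out
}
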