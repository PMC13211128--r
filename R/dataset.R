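#' Epoch dataset container
#'
#' The in-memory container for scored 30-s epochs: per-modality signal
#' arrays of dim `(N, channels, samples)`, integer stage labels (0..4 in the
#' order W, N1, N2, N3, REM), subject identifiers, the originating
#' [dataset_profile()] and a record of applied preprocessing steps.
#'
#' @param eeg numeric array `(N, C_eeg, L_eeg)` or `NULL`.
#' @param eog numeric array `(N, C_eog, L_eog)` or `NULL` (EEG-only profiles).
#' @param labels integer vector length N, values 0..4, or `NULL` when
#'   unscored.
#' @param subject_ids vector length N.
#' @param profile a `dataset_profile`.
#' @param fs_eeg,fs_eog current sampling rates (may differ from the profile
#'   after harmonization).
#' @param preprocessing_flags character vector of applied steps.
#' @return an object of class `epoch_dataset`.
#' @export
epoch_dataset <- function(eeg, eog, labels, subject_ids, profile,
                          fs_eeg = profile$fs_eeg, fs_eog = profile$fs_eog,
                          preprocessing_flags = character()) {
  stopifnot(inherits(profile, "dataset_profile"))
  n <- if (!is.null(eeg)) dim(eeg)[1L] else dim(eog)[1L]
  for (arr in list(eeg, eog)) {
    if (!is.null(arr)) {
      stopifnot(length(dim(arr)) == 3L)
      if (dim(arr)[1L] != n) stopf("modality arrays disagree in epoch count")
    }
  }
  if (!is.null(labels)) {
    labels <- check_labels(labels)
    if (length(labels) != n) stopf("labels length %d != %d epochs", length(labels), n)
  }
  if (length(subject_ids) != n) stopf("subject_ids length %d != %d epochs", length(subject_ids), n)
  structure(list(eeg = eeg, eog = eog, labels = labels,
                 subject_ids = subject_ids, profile = profile,
                 fs_eeg = fs_eeg, fs_eog = fs_eog,
                 preprocessing_flags = preprocessing_flags),
            class = "epoch_dataset")
}

#' @export
print.epoch_dataset <- function(x, ...) {
  cat(sprintf("<epoch_dataset: %d epochs, %d subjects, profile %s>\n",
              n_epochs(x), length(unique(x$subject_ids)), x$profile$name))
  if (!is.null(x$eeg)) cat(sprintf("  eeg: %s @ %g Hz\n", paste(dim(x$eeg), collapse = "x"), x$fs_eeg))
  if (!is.null(x$eog)) cat(sprintf("  eog: %s @ %g Hz\n", paste(dim(x$eog), collapse = "x"), x$fs_eog))
  if (!is.null(x$labels)) {
    tab <- table(factor(stage_name(x$labels), levels = STAGES))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  cat(sprintf("  preprocessing: %s\n",
              if (length(x$preprocessing_flags)) paste(x$preprocessing_flags, collapse = " -> ") else "(raw)"))
  invisible(x)
}

#' @rdname epoch_dataset
#' @param x an `epoch_dataset`.
#' @export
n_epochs <- function(x) {
  if (!is.null(x$eeg)) dim(x$eeg)[1L] else if (!is.null(x$eog)) dim(x$eog)[1L] else 0L
}

#' Subset an epoch dataset
#' @param dataset an `epoch_dataset`.
#' @param idx integer epoch indices.
#' @return the subset `epoch_dataset`.
#' @export
dataset_subset <- function(dataset, idx) {
  epoch_dataset(
    eeg = if (!is.null(dataset$eeg)) dataset$eeg[idx, , , drop = FALSE],
    eog = if (!is.null(dataset$eog)) dataset$eog[idx, , , drop = FALSE],
    labels = if (!is.null(dataset$labels)) dataset$labels[idx],
    subject_ids = dataset$subject_ids[idx],
    profile = dataset$profile,
    fs_eeg = dataset$fs_eeg, fs_eog = dataset$fs_eog,
    preprocessing_flags = dataset$preprocessing_flags)
}

# Channel-first batch view for the network: (C, L, B) per modality.
dataset_batch <- function(dataset, idx) {
  out <- list(labels = if (!is.null(dataset$labels)) dataset$labels[idx])
  if (!is.null(dataset$eeg)) out$eeg <- aperm(dataset$eeg[idx, , , drop = FALSE], c(2L, 3L, 1L))
  if (!is.null(dataset$eog)) out$eog <- aperm(dataset$eog[idx, , , drop = FALSE], c(2L, 3L, 1L))
  out
}

#' Combine epoch datasets row-wise
#' @param ... `epoch_dataset` objects sharing a profile and rates.
#' @return the concatenated `epoch_dataset`.
#' @export
dataset_rbind <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  bind_mod <- function(field) {
    arrs <- lapply(parts, `[[`, field)
    if (is.null(arrs[[1L]])) return(NULL)
    d <- dim(arrs[[1L]])[-1L]
    tot <- sum(vapply(arrs, function(a) dim(a)[1L], 0L))
    out <- array(NA_real_, c(tot, d))
    at <- 0L
    for (a in arrs) {
      out[at + seq_len(dim(a)[1L]), , ] <- a
      at <- at + dim(a)[1L]
    }
    out
  }
  p1 <- parts[[1L]]
  epoch_dataset(
    eeg = bind_mod("eeg"), eog = bind_mod("eog"),
    labels = if (!is.null(p1$labels)) unlist(lapply(parts, `[[`, "labels")),
    subject_ids = unlist(lapply(parts, `[[`, "subject_ids")),
    profile = p1$profile, fs_eeg = p1$fs_eeg, fs_eog = p1$fs_eog,
    preprocessing_flags = p1$preprocessing_flags)
}
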