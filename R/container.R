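# Dataset container and best-effort EDF ingestion.
#
# The container carries the documented schema (modality arrays, labels,
# subject ids, profile attributes, preprocessing flags, schema_version) in a
# single RDS file: the supported R stack has no HDF5 binding, so the HDF5
# layout is mirrored in RDS with identical group/attribute names and a
# version check on read. Round-trips are bit-exact.

CONTAINER_VERSION <- "1.0"

validate_container <- function(x) {
  if (is.null(x$schema_version)) stopf("not a dataset container (no schema_version)")
  if (!identical(x$schema_version, CONTAINER_VERSION)) {
    stopf("container schema_version %s unsupported (expected %s)",
          x$schema_version, CONTAINER_VERSION)
  }
  n <- if (!is.null(x$eeg)) dim(x$eeg)[1L] else dim(x$eog)[1L]
  for (f in c("eeg", "eog")) {
    if (!is.null(x[[f]]) && (length(dim(x[[f]])) != 3L || dim(x[[f]])[1L] != n)) {
      stopf("container group '%s' has inconsistent shape", f)
    }
  }
  if (!is.null(x$labels)) {
    if (length(x$labels) != n) stopf("labels length mismatch")
    if (!all(x$labels %in% 0:4)) stopf("container labels out of range 0..4")
  }
  if (length(x$subject_ids) != n) stopf("subject_ids length mismatch")
  invisible(TRUE)
}

#' Write / read the epoch-dataset container
#'
#' Lossless (bit-exact) serialization of an [epoch_dataset()] with schema
#' validation and a version check on read; tampered containers (e.g. labels
#' out of range) are rejected.
#'
#' @param dataset an `epoch_dataset`.
#' @param path file path (conventionally `.rds`).
#' @return `write_container` returns `path` invisibly; `read_container`
#'   the `epoch_dataset`.
#' @export
write_container <- function(dataset, path) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  obj <- list(schema_version = CONTAINER_VERSION,
              profile = unclass(dataset$profile),
              eeg = dataset$eeg, eog = dataset$eog,
              labels = dataset$labels, subject_ids = dataset$subject_ids,
              fs_eeg = dataset$fs_eeg, fs_eog = dataset$fs_eog,
              preprocessing_flags = dataset$preprocessing_flags)
  validate_container(obj)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  obj <- readRDS(path)
  validate_container(obj)
  profile <- structure(obj$profile, class = "dataset_profile")
  epoch_dataset(eeg = obj$eeg, eog = obj$eog, labels = obj$labels,
                subject_ids = obj$subject_ids, profile = profile,
                fs_eeg = obj$fs_eeg, fs_eog = obj$fs_eog,
                preprocessing_flags = obj$preprocessing_flags)
}

# ---- EDF (16-bit European Data Format), best-effort ------------------------

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Minimal continuous EDF writer (1-s data records, 16-bit samples scaled to
#' each channel's physical range). Used to build on-the-fly fixtures for the
#' ingestion path; quantization limits round-trip fidelity to the 16-bit
#' grid.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @param channel_labels optional labels (defaults `EEG1..`, `EOG1..`).
#' @return `path` invisibly.
#' @export
write_edf <- function(rec, path, channel_labels = NULL) {
  stopifnot(inherits(rec, "recording"))
  sigs <- list()
  fs <- c()
  for (ch in seq_len(nrow(rec$eeg))) {
    sigs <- c(sigs, list(rec$eeg[ch, ]))
    fs <- c(fs, rec$fs_eeg)
  }
  if (!is.null(rec$eog)) {
    for (ch in seq_len(nrow(rec$eog))) {
      sigs <- c(sigs, list(rec$eog[ch, ]))
      fs <- c(fs, rec$fs_eog)
    }
  }
  ns <- length(sigs)
  if (is.null(channel_labels)) {
    channel_labels <- c(paste0("EEG", seq_len(nrow(rec$eeg))),
                        if (!is.null(rec$eog)) paste0("EOG", seq_len(nrow(rec$eog))))
  }
  stopifnot(length(channel_labels) == ns)
  if (any(abs(fs - round(fs)) > 1e-9)) stopf("EDF writer needs integer Hz rates")
  n_rec <- min(floor(lengths(sigs) / fs))
  if (n_rec < 1) stopf("recording shorter than one 1-s data record")
  pmaxs <- vapply(sigs, function(s) max(abs(s), 1e-6), 0)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wchar <- function(x, w) writeChar(pad_field(x, w), con, nchars = w, eos = NULL)
  wchar("0", 8L)
  wchar(sprintf("subject %s", rec$subject_id), 80L)
  wchar("synthetic recording", 80L)
  wchar("01.01.26", 8L)
  wchar("00.00.00", 8L)
  wchar(256L + ns * 256L, 8L)
  wchar("", 44L)
  wchar(n_rec, 8L)
  wchar(1L, 8L)
  wchar(ns, 4L)
  for (lab in channel_labels) wchar(lab, 16L)
  for (i in seq_len(ns)) wchar("synthetic", 80L)
  for (i in seq_len(ns)) wchar("uV", 8L)
  for (i in seq_len(ns)) wchar(sprintf("%.6g", -pmaxs[i]), 8L)
  for (i in seq_len(ns)) wchar(sprintf("%.6g", pmaxs[i]), 8L)
  for (i in seq_len(ns)) wchar(-32768L, 8L)
  for (i in seq_len(ns)) wchar(32767L, 8L)
  for (i in seq_len(ns)) wchar("", 80L)
  for (i in seq_len(ns)) wchar(fs[i], 8L)
  for (i in seq_len(ns)) wchar("", 32L)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- sigs[[i]][(r - 1L) * fs[i] + seq_len(fs[i])]
      dig <- as.integer(round((seg + pmaxs[i]) / (2 * pmaxs[i]) * 65535 - 32768))
      dig <- pmin(pmax(dig, -32768L), 32767L)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rstr <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rnum <- function(w) as.numeric(rstr(w))
  version <- rstr(8L)
  patient <- rstr(80L)
  rec_id <- rstr(80L)
  rstr(8L); rstr(8L); rnum(8L); rstr(44L)
  n_rec <- rnum(8L)
  dur <- rnum(8L)
  ns <- as.integer(rnum(4L))
  labels <- vapply(seq_len(ns), function(i) rstr(16L), "")
  for (i in seq_len(ns)) rstr(80L)
  units <- vapply(seq_len(ns), function(i) rstr(8L), "")
  pmin_ <- vapply(seq_len(ns), function(i) rnum(8L), 0)
  pmax_ <- vapply(seq_len(ns), function(i) rnum(8L), 0)
  dmin <- vapply(seq_len(ns), function(i) rnum(8L), 0)
  dmax <- vapply(seq_len(ns), function(i) rnum(8L), 0)
  for (i in seq_len(ns)) rstr(80L)
  spr <- vapply(seq_len(ns), function(i) as.integer(rnum(8L)), 0L)
  for (i in seq_len(ns)) rstr(32L)
  sigs <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
      phys <- pmin_[i] + (dig - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      sigs[[i]][(r - 1L) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  list(labels = labels, units = units, fs = spr / dur, signals = sigs,
       patient = patient, recording = rec_id, version = version)
}

#' Ingest an EDF file as a recording
#'
#' Best-effort reader for continuous 16-bit EDF. Channels are selected and
#' assigned to modalities via `channel_map`; signals are returned in
#' physical units (microvolts) at their native rates. All channels mapped to
#' one modality must share a sampling rate.
#'
#' @param path EDF file.
#' @param channel_map list with character vectors `eeg` and (optionally)
#'   `eog` naming the EDF signal labels to use, in order.
#' @param subject_id identifier for the resulting [recording()].
#' @return a [recording()].
#' @export
ingest_edf <- function(path, channel_map, subject_id = basename(path)) {
  raw <- read_edf_raw(path)
  pick <- function(wanted) {
    idx <- match(wanted, raw$labels)
    if (anyNA(idx)) {
      stopf("channel(s) %s not in EDF; available: %s",
            paste(wanted[is.na(idx)], collapse = ", "),
            paste(raw$labels, collapse = ", "))
    }
    idx
  }
  ie <- pick(channel_map$eeg)
  if (length(unique(raw$fs[ie])) != 1L) stopf("EEG channels have mixed rates")
  eeg <- do.call(rbind, raw$signals[ie])
  eog <- NULL
  fs_eog <- raw$fs[ie[1L]]
  if (!is.null(channel_map$eog) && length(channel_map$eog)) {
    io <- pick(channel_map$eog)
    if (length(unique(raw$fs[io])) != 1L) stopf("EOG channels have mixed rates")
    eog <- do.call(rbind, raw$signals[io])
    fs_eog <- raw$fs[io[1L]]
  }
  recording(eeg = eeg, eog = eog, fs_eeg = raw$fs[ie[1L]], fs_eog = fs_eog,
            subject_id = subject_id)
}

#' Map legacy stage codes to the five-class scheme
#'
#' Converts textual hypnogram codes to integer stages, merging the legacy
#' R&K stages 3 and 4 into N3. Recognized codes: `W`/`0`/`Wake`; `1`/`N1`;
#' `2`/`N2`; `3`, `4`, `N3`; `5`, `R`, `REM`. Unknown codes are dropped
#' (with a warning) or raise an error depending on `on_unknown`.
#'
#' @param codes character vector of stage codes (one per epoch).
#' @param on_unknown `"drop"` or `"error"`.
#' @return integer labels 0..4 (unknown codes removed when dropping); the
#'   kept positions are attached as attribute `kept`.
#' @export
map_stage_codes <- function(codes, on_unknown = c("drop", "error")) {
  on_unknown <- match.arg(on_unknown)
  lut <- c("W" = 0L, "WAKE" = 0L, "0" = 0L,
           "1" = 1L, "N1" = 1L,
           "2" = 2L, "N2" = 2L,
           "3" = 3L, "4" = 3L, "N3" = 3L,
           "5" = 4L, "R" = 4L, "REM" = 4L)
  mapped <- lut[toupper(trimws(codes))]
  bad <- is.na(mapped)
  if (any(bad)) {
    if (on_unknown == "error") stopf("unknown stage code(s): %s",
                                     paste(unique(codes[bad]), collapse = ", "))
    warnf("dropping %d epoch(s) with unknown stage codes", sum(bad))
  }
  out <- unname(mapped[!bad])
  attr(out, "kept") <- unname(which(!bad))
  out
}
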