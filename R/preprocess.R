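# Signal conditioning. The pipeline is deliberately minimal: first-order
# least-squares detrending per channel over the whole recording, z-score
# normalization with statistics computed per recording (not per epoch),
# segmentation into contiguous non-overlapping 30-s epochs (trailing
# remainder dropped), and optional polyphase rate harmonization for
# mixed-rate montages. No filtering and no epoch exclusion anywhere.

#' Raw multichannel recording
#'
#' @param eeg numeric matrix `channels x samples`.
#' @param eog numeric matrix or `NULL`.
#' @param fs_eeg,fs_eog sampling rates in Hz (> 0).
#' @param subject_id identifier.
#' @param units signal units; microvolts throughout.
#' @param preprocessing_flags record of applied steps.
#' @return an object of class `recording`.
#' @export
recording <- function(eeg, eog = NULL, fs_eeg, fs_eog = fs_eeg,
                      subject_id = 1L, units = "uV",
                      preprocessing_flags = character()) {
  stopifnot(is.matrix(eeg), fs_eeg > 0, fs_eog > 0)
  if (!is.null(eog)) stopifnot(is.matrix(eog))
  structure(list(eeg = eeg, eog = eog, fs_eeg = fs_eeg, fs_eog = fs_eog,
                 subject_id = subject_id, units = units,
                 preprocessing_flags = preprocessing_flags),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording subject %s: eeg %dch x %d @ %g Hz", x$subject_id,
              nrow(x$eeg), ncol(x$eeg), x$fs_eeg))
  if (!is.null(x$eog)) cat(sprintf(", eog %dch x %d @ %g Hz", nrow(x$eog), ncol(x$eog), x$fs_eog))
  cat(sprintf(", steps: %s>\n",
              if (length(x$preprocessing_flags)) paste(x$preprocessing_flags, collapse = " -> ") else "raw"))
  invisible(x)
}

#' Remove a least-squares line from a signal
#'
#' Fits a first-order polynomial `a + b t` by least squares and subtracts
#' it, removing slow baseline drift while leaving oscillatory content
#' untouched (the residual input minus output is exactly a line).
#'
#' @param x numeric vector, length >= 2.
#' @return detrended vector of the same length.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) stopf("detrend_linear needs at least 2 samples, got %d", n)
  t <- seq_len(n)
  tc <- t - mean(t)
  b <- sum(tc * x) / sum(tc * tc)
  a <- mean(x) - b * mean(t)
  x - (a + b * t)
}

detrend_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  rec$eeg <- t(apply(rec$eeg, 1L, detrend_linear))
  if (!is.null(rec$eog)) rec$eog <- t(apply(rec$eog, 1L, detrend_linear))
  rec$preprocessing_flags <- c(rec$preprocessing_flags, "detrend")
  rec
}

#' Z-score a recording
#'
#' Standardizes each channel using its mean and standard deviation computed
#' over the entire recording. Zero-variance channels cannot be standardized;
#' they are passed through as zeros with a warning so batch shapes stay
#' valid.
#'
#' @param rec a [recording()].
#' @return the standardized `recording` with a `zscore` flag appended.
#' @export
zscore_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  zs <- function(mat, label) {
    for (ch in seq_len(nrow(mat))) {
      m <- mean(mat[ch, ])
      s <- stats::sd(mat[ch, ])
      if (!is.finite(s) || s == 0) {
        warnf("%s channel %d has zero variance; passed through as zeros", label, ch)
        mat[ch, ] <- 0
      } else {
        mat[ch, ] <- (mat[ch, ] - m) / s
      }
    }
    mat
  }
  rec$eeg <- zs(rec$eeg, "eeg")
  if (!is.null(rec$eog)) rec$eog <- zs(rec$eog, "eog")
  rec$preprocessing_flags <- c(rec$preprocessing_flags, "zscore")
  rec
}

#' Standard preprocessing pipeline
#'
#' Detrend then z-score, in that order, each over the whole recording.
#' Segmentation ([segment_epochs()]) and, for mixed-rate montages,
#' harmonization ([harmonize_rates()]) follow. These are the only steps; no
#' filtering or signal cleaning is applied.
#'
#' @param rec a [recording()].
#' @return the preprocessed `recording`.
#' @export
preprocess_recording <- function(rec) {
  zscore_recording(detrend_recording(rec))
}

#' Segment a recording into epochs
#'
#' Cuts contiguous non-overlapping windows of `epoch_s` seconds starting at
#' sample 0; a trailing partial epoch is dropped. The epoch count is
#' `floor(samples / (fs * epoch_s))` (the minimum across modalities).
#'
#' @param rec a [recording()].
#' @param epoch_s epoch length in seconds.
#' @param profile optional [dataset_profile()] to attach; inferred from the
#'   recording otherwise.
#' @return an unlabeled [epoch_dataset()] (possibly with zero epochs, with a
#'   warning, when the recording is shorter than one epoch).
#' @export
segment_epochs <- function(rec, epoch_s = 30, profile = NULL) {
  stopifnot(inherits(rec, "recording"))
  spe_eeg <- rec$fs_eeg * epoch_s
  if (abs(spe_eeg - round(spe_eeg)) > 1e-9) stopf("fs x epoch_s must be integral")
  spe_eeg <- as.integer(round(spe_eeg))
  n <- ncol(rec$eeg) %/% spe_eeg
  spe_eog <- NULL
  if (!is.null(rec$eog)) {
    spe_eog <- as.integer(round(rec$fs_eog * epoch_s))
    n <- min(n, ncol(rec$eog) %/% spe_eog)
  }
  if (n == 0L) warnf("recording shorter than one epoch; returning an empty dataset")
  cut_mod <- function(mat, spe) {
    C <- nrow(mat)
    out <- array(0, c(n, C, spe))
    for (i in seq_len(n)) {
      out[i, , ] <- mat[, (i - 1L) * spe + seq_len(spe), drop = FALSE]
    }
    out
  }
  if (is.null(profile)) {
    profile <- dataset_profile("custom", eeg_channels = nrow(rec$eeg),
                               eog_channels = if (is.null(rec$eog)) 0L else nrow(rec$eog),
                               fs_eeg = rec$fs_eeg, fs_eog = rec$fs_eog,
                               epoch_s = epoch_s)
  }
  epoch_dataset(eeg = cut_mod(rec$eeg, spe_eeg),
                eog = if (!is.null(rec$eog)) cut_mod(rec$eog, spe_eog),
                labels = NULL,
                subject_ids = rep(rec$subject_id, n),
                profile = profile,
                fs_eeg = rec$fs_eeg, fs_eog = rec$fs_eog,
                preprocessing_flags = c(rec$preprocessing_flags, "segment"))
}

# greatest common divisor for rational rate ratios
gcd2 <- function(a, b) { while (b > 0) { t <- a %% b; a <- b; b <- t }; a }

#' Rational-rate polyphase resampling of a vector
#'
#' Resamples by the rational factor `p/q`: zero-stuff by `p`, apply a
#' windowed-sinc (Hamming) lowpass at the tighter of the two Nyquist rates,
#' decimate by `q`. Edges are handled by reflection so that bandlimited
#' tones survive end to end; passband energy is preserved to well within 1%.
#'
#' @param x numeric vector.
#' @param p,q positive integers (upsampling / downsampling factors).
#' @param half_width filter half-width in multiples of `max(p, q)` taps.
#' @return resampled vector of length `floor(length(x) * p / q)`.
#' @export
resample_poly <- function(x, p, q, half_width = 10L) {
  stopifnot(p >= 1, q >= 1, p == round(p), q == round(q))
  p <- as.integer(p); q <- as.integer(q)
  g <- gcd2(p, q)
  p <- p %/% g; q <- q %/% g
  n <- length(x)
  Lout <- (n * p) %/% q
  if (p == 1L && q == 1L) return(x)
  H <- half_width * max(p, q)           # filter half-width (upsampled samples)
  m <- ceiling(H / p) + 1L              # reflection pad (original samples)
  if (m >= n) stopf("signal too short (%d samples) to resample with this filter", n)
  xp <- c(rev(x[2:(m + 1L)]), x, rev(x[(n - m):(n - 1L)]))
  np <- length(xp)
  u <- numeric(np * p)
  u[(seq_len(np) - 1L) * p + 1L] <- xp
  k <- seq.int(-H, H)
  fc <- 1 / (2 * max(p, q))             # cycles per upsampled sample
  h <- 2 * fc * ifelse(k == 0L, 1, sin(2 * pi * fc * k) / (2 * pi * fc * k))
  h <- h * (0.54 + 0.46 * cos(pi * k / H))   # Hamming window
  h <- h / sum(h) * p                   # unit DC gain, upsampling compensation
  yf <- stats::convolve(u, rev(h), type = "open")   # full convolution, FFT-based
  # sample i of the output sits at upsampled index m*p + (i-1)*q + 1; the
  # full convolution adds a delay of H samples
  idx <- H + m * p + (seq_len(Lout) - 1L) * q + 1L
  yf[idx]
}

#' Harmonize modality sampling rates
#'
#' Brings every modality of an [epoch_dataset()] to a common sampling rate
#' so the two branch feature maps align in time (the fused concatenation
#' needs equal temporal length after the backbone's /32 downsampling).
#' Default target is the highest modality rate, i.e. upsampling only.
#'
#' @param dataset an `epoch_dataset`.
#' @param target_fs target rate in Hz; defaults to the maximum modality rate.
#' @param allow_downsample permit `target_fs` below a modality rate.
#' @return the harmonized `epoch_dataset` (bit-identical pass-through for
#'   modalities already at the target rate).
#' @export
harmonize_rates <- function(dataset, target_fs = NULL, allow_downsample = FALSE) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  rates <- c(dataset$fs_eeg, if (!is.null(dataset$eog)) dataset$fs_eog)
  target_fs <- target_fs %||% max(rates)
  if (!allow_downsample && target_fs < max(rates)) {
    stopf("target_fs %g below the highest modality rate %g (set allow_downsample)", target_fs, max(rates))
  }
  ratio_pq <- function(fs) {
    r <- target_fs / fs
    # accept ratios rational in small integers (sampling rates are integral
    # in practice); reject e.g. irrational targets
    for (den in 1:1000) {
      if (abs(r * den - round(r * den)) < 1e-9) return(c(as.integer(round(r * den)), den))
    }
    stopf("rate ratio %g/%g is not usably rational", target_fs, fs)
  }
  resample_mod <- function(arr, fs) {
    if (abs(fs - target_fs) < 1e-12) return(arr)
    pq <- ratio_pq(fs)
    d <- dim(arr)
    Lout <- (d[3L] * pq[1L]) %/% pq[2L]
    out <- array(0, c(d[1L], d[2L], Lout))
    for (i in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
      out[i, ch, ] <- resample_poly(arr[i, ch, ], pq[1L], pq[2L])
    }
    out
  }
  changed <- FALSE
  if (abs(dataset$fs_eeg - target_fs) > 1e-12) {
    dataset$eeg <- resample_mod(dataset$eeg, dataset$fs_eeg)
    dataset$fs_eeg <- target_fs
    changed <- TRUE
  }
  if (!is.null(dataset$eog) && abs(dataset$fs_eog - target_fs) > 1e-12) {
    dataset$eog <- resample_mod(dataset$eog, dataset$fs_eog)
    dataset$fs_eog <- target_fs
    changed <- TRUE
  }
  if (changed) {
    dataset$preprocessing_flags <- c(dataset$preprocessing_flags,
                                     sprintf("harmonize:%gHz", target_fs))
  }
  dataset
}
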