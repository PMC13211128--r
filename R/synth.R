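# Stage-conditioned synthetic polysomnography.
#
# The generator emulates the statistical structure the staging pipeline
# relies on, not biophysics: a 1/f (beta = 1) background plus white sensor
# noise, stage-specific narrowband oscillations and transient events
# (alpha in W, theta in N1, spindles and a K-complex in N2, high-amplitude
# delta in N3, rapid-eye-movement bursts and ocular events in the EOG),
# per-subject gain / baseline-drift / noise heterogeneity, and Markov
# hypnogram-like stage sequences. All amplitudes are in microvolts. Every
# generator is a pure function of its seed(s).

#' Stage profiles of the synthetic generator
#'
#' Describes, per stage, the narrowband oscillations (low Hz, high Hz,
#' amplitude in microvolts), the transient events and the 1/f background
#' exponent. The `signature` entry names the band (and modality) whose
#' relative power increase over the background is designed to dominate for
#' that stage; the spectral-fidelity tests check exactly this.
#'
#' @param tweaks optional named list (by stage) of multipliers, e.g.
#'   `list(N3 = list(band_amp = 0.5))` halves the N3 delta amplitude and
#'   `list(N2 = list(event_amp = 0.6))` scales the N2 transients. Used to
#'   plant class-conditional distribution shifts for adaptation experiments.
#' @return named list of stage profile descriptors.
#' @export
stage_profiles <- function(tweaks = NULL) {
  p <- list(
    W = list(
      bands = list(c(8, 12, 20)),
      events = list(list(type = "blink", target = "eog", n = c(1L, 3L),
                         dur = c(0.2, 0.4), freq = NULL, amp = 100)),
      eog_leak = 0,
      signature = list(modality = "eeg", band = c(8, 12))),
    N1 = list(
      bands = list(c(4, 7, 20)),
      events = list(list(type = "slow_eye", target = "eog", n = c(1L, 2L),
                         dur = c(3, 6), freq = c(0.2, 0.5), amp = 30)),
      eog_leak = 0,
      signature = list(modality = "eeg", band = c(4, 7))),
    N2 = list(
      bands = list(c(4, 7, 5)),
      events = list(
        list(type = "spindle", target = "eeg", n = c(3L, 5L),
             dur = c(0.5, 1.5), freq = c(12, 14), amp = 30),
        list(type = "kcomplex", target = "eeg", n = c(1L, 1L),
             dur = c(0.7, 0.9), freq = NULL, amp = 60)),
      eog_leak = 0,
      signature = list(modality = "eeg", band = c(12, 14))),
    N3 = list(
      bands = list(c(0.5, 2, 60)),
      events = list(),
      # frontal slow waves contaminate the EOG leads; this also plants the
      # common component that drives the stage-wise correlation analysis
      eog_leak = 0.5,
      signature = list(modality = "eeg", band = c(0.5, 2))),
    REM = list(
      bands = list(c(4, 7, 6)),
      events = list(list(type = "rem_burst", target = "eog", n = c(5L, 9L),
                         dur = c(0.4, 1.0), freq = c(1, 3), amp = 175)),
      eog_leak = 0,
      signature = list(modality = "eog", band = c(0.5, 5))))
  for (nm in names(p)) p[[nm]]$background_exponent <- 1
  if (!is.null(tweaks)) {
    for (st in names(tweaks)) {
      if (!st %in% names(p)) stopf("unknown stage '%s' in tweaks", st)
      tw <- tweaks[[st]]
      if (!is.null(tw$band_amp)) {
        p[[st]]$bands <- lapply(p[[st]]$bands, function(b) c(b[1:2], b[3] * tw$band_amp))
      }
      if (!is.null(tw$event_amp)) {
        p[[st]]$events <- lapply(p[[st]]$events, function(e) { e$amp <- e$amp * tw$event_amp; e })
      }
    }
  }
  p
}

validate_stage_profiles <- function(profiles, profile) {
  for (nm in names(profiles)) {
    sp <- profiles[[nm]]
    for (b in sp$bands) {
      if (b[1] <= 0 || b[2] <= b[1]) stopf("stage %s: invalid band edges", nm)
      if (b[2] >= profile$fs_eeg / 2) stopf("stage %s: band edge %g Hz at/above EEG Nyquist", nm, b[2])
      if (b[3] <= 0) stopf("stage %s: non-positive band amplitude", nm)
    }
    for (e in sp$events) {
      if (!is.null(e$freq) && e$target == "eeg" && e$freq[2] >= profile$fs_eeg / 2) {
        stopf("stage %s: event frequency above EEG Nyquist", nm)
      }
      if (!is.null(e$freq) && e$target == "eog" && profile$eog_channels > 0 &&
          e$freq[2] >= profile$fs_eog / 2) {
        stopf("stage %s: event frequency above EOG Nyquist", nm)
      }
    }
  }
  invisible(TRUE)
}

#' Subject parameters
#'
#' Per-subject heterogeneity applied to every epoch of the subject: a
#' multiplicative gain, a linear baseline drift (microvolts per second), a
#' slow sinusoidal drift wave and an additive white-noise level.
#'
#' @param gain multiplicative channel scale (> 0).
#' @param drift_slope linear baseline slope, microvolts / s.
#' @param drift_amp,drift_period slow sinusoid amplitude (microvolts) and
#'   period (s).
#' @param noise_sd white noise standard deviation in microvolts (>= 0).
#' @param id subject identifier.
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(gain = 1, drift_slope = 0, drift_amp = 0,
                           drift_period = 120, noise_sd = 2, id = 1L) {
  if (gain <= 0) stopf("gain must be positive")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (drift_period <= 0) stopf("drift_period must be positive")
  structure(list(gain = gain, drift_slope = drift_slope, drift_amp = drift_amp,
                 drift_period = drift_period, noise_sd = noise_sd, id = id),
            class = "subject_params")
}

#' Ranges for drawing subject parameters
#'
#' The cohort generator draws each subject uniformly from these ranges;
#' defaults span a 4-fold gain spread, drifts slow enough to survive
#' detrending only partially (the sinusoidal component), and noise between
#' 1 and 3 microvolts.
#'
#' @param gain,drift_slope,drift_amp,drift_period,noise_sd length-2 ranges.
#' @return a named list of ranges.
#' @export
subject_param_ranges <- function(gain = c(0.5, 2), drift_slope = c(-0.05, 0.05),
                                 drift_amp = c(0, 20), drift_period = c(60, 300),
                                 noise_sd = c(1, 3)) {
  list(gain = gain, drift_slope = drift_slope, drift_amp = drift_amp,
       drift_period = drift_period, noise_sd = noise_sd)
}

draw_subject_params <- function(ranges, seed, id) {
  with_seed(seed, {
    u <- function(r) stats::runif(1, r[1], r[2])
    subject_params(gain = u(ranges$gain), drift_slope = u(ranges$drift_slope),
                   drift_amp = u(ranges$drift_amp), drift_period = u(ranges$drift_period),
                   noise_sd = u(ranges$noise_sd), id = id)
  })
}

#' Deterministic drift component
#'
#' @param subject a [subject_params()].
#' @param t time points in seconds.
#' @return drift values in microvolts (before the subject gain).
#' @export
drift_signal <- function(subject, t) {
  subject$drift_slope * t +
    subject$drift_amp * sin(2 * pi * t / subject$drift_period)
}

# 1/f^beta noise of length n scaled to a target RMS, via spectral shaping.
colored_noise <- function(n, beta = 1, rms = 10) {
  nf <- n %/% 2L
  k <- 2:(nf + 1L)
  vals <- (stats::rnorm(nf) + 1i * stats::rnorm(nf)) * (k - 1)^(-beta / 2)
  X <- rep(0 + 0i, n)
  X[k] <- vals
  m <- n + 2L - k
  same <- m == k
  X[m[!same]] <- Conj(X[k[!same]])
  X[k[same]] <- Re(X[k[same]])
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x * (rms / s)
  x
}

hann_win <- function(m) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = m))

# Draw the transient events of one epoch; returns a list of placed events.
draw_events <- function(events, epoch_s) {
  placed <- list()
  for (e in events) {
    n <- if (e$n[1] == e$n[2]) e$n[1] else sample(seq.int(e$n[1], e$n[2]), 1L)
    for (i in seq_len(n)) {
      dur <- stats::runif(1, e$dur[1], e$dur[2])
      center <- stats::runif(1, dur / 2 + 0.5, epoch_s - dur / 2 - 0.5)
      freq <- if (!is.null(e$freq)) stats::runif(1, e$freq[1], e$freq[2]) else NA_real_
      phase <- stats::runif(1, 0, 2 * pi)
      placed[[length(placed) + 1L]] <- list(type = e$type, target = e$target,
                                            center = center, dur = dur,
                                            freq = freq, amp = e$amp, phase = phase)
    }
  }
  placed
}

# Render one event into a zero buffer of length L at rate fs.
render_event <- function(ev, fs, L) {
  out <- numeric(L)
  i0 <- max(1L, floor((ev$center - ev$dur / 2) * fs) + 1L)
  i1 <- min(L, ceiling((ev$center + ev$dur / 2) * fs))
  if (i1 <= i0) return(out)
  idx <- i0:i1
  tt <- (idx - 1) / fs
  w <- hann_win(length(idx))
  out[idx] <- switch(ev$type,
    spindle = ev$amp * sin(2 * pi * ev$freq * tt + ev$phase) * w,
    blink = ev$amp * w,
    slow_eye = ev$amp * sin(2 * pi * ev$freq * tt + ev$phase) * w,
    rem_burst = ev$amp * sin(2 * pi * ev$freq * tt + ev$phase) * w,
    # one full sine cycle under a Hann window: a biphasic pulse
    kcomplex = ev$amp * sin(2 * pi * (idx - i0) / length(idx)) * w,
    stopf("unknown event type '%s'", ev$type))
  out
}

#' Generate one stage-conditioned epoch
#'
#' Builds the raw (unpreprocessed) signals of a single 30-s epoch for one
#' stage: per-channel 1/f background and white noise, shared narrowband
#' oscillations, transient events, subject drift and gain. REM epochs place
#' their eye-movement bursts with opposite polarity on the two EOG channels
#' when the montage has two.
#'
#' @param stage stage name (`"W"`, `"N1"`, `"N2"`, `"N3"`, `"REM"`) or code 0..4.
#' @param profile a [dataset_profile()].
#' @param subject a [subject_params()].
#' @param seed optional seed making the epoch fully reproducible; when `NULL`
#'   the current RNG stream is consumed (used by the cohort generator).
#' @param t_offset epoch start time in seconds (drift continuity across a
#'   recording).
#' @param components character subset of
#'   `c("background", "oscillations", "events", "noise", "drift")`; removing
#'   components yields the degenerate signals used in tests.
#' @param profiles stage profile set, see [stage_profiles()].
#' @param background_rms RMS of the 1/f background in microvolts.
#' @return list with `eeg` (`C_eeg x L_eeg` matrix) and `eog`
#'   (`C_eog x L_eog` matrix, `NULL` when the profile has no EOG).
#' @export
generate_epoch <- function(stage, profile, subject = subject_params(),
                           seed = NULL, t_offset = 0,
                           components = c("background", "oscillations",
                                          "events", "noise", "drift"),
                           profiles = stage_profiles(), background_rms = 10) {
  stopifnot(inherits(profile, "dataset_profile"))
  if (is.numeric(stage)) stage <- stage_name(stage)
  stage <- match.arg(stage, STAGES)
  sp <- profiles[[stage]]
  validate_stage_profiles(profiles[stage], profile)
  with_seed(seed, {
    L_eeg <- profile$samples_eeg
    L_eog <- profile$samples_eog
    t_eeg <- t_offset + (seq_len(L_eeg) - 1) / profile$fs_eeg
    t_eog <- t_offset + (seq_len(L_eog) - 1) / profile$fs_eog

    # shared oscillation parameters (one draw per band per epoch)
    osc_eeg <- numeric(L_eeg)
    osc_leak <- numeric(L_eog)
    for (b in sp$bands) {
      f <- stats::runif(1, b[1], b[2])
      ph <- stats::runif(1, 0, 2 * pi)
      if ("oscillations" %in% components) {
        osc_eeg <- osc_eeg + b[3] * sin(2 * pi * f * t_eeg + ph)
        if (sp$eog_leak > 0 && profile$eog_channels > 0) {
          osc_leak <- osc_leak + sp$eog_leak * b[3] * sin(2 * pi * f * t_eog + ph)
        }
      }
    }

    # draws are consumed even when events are disabled so that component
    # subsets of the same seed share an identical noise stream
    evs <- draw_events(sp$events, profile$epoch_s)
    if (!("events" %in% components)) evs <- list()
    ev_eeg <- numeric(L_eeg)
    ev_eog <- numeric(L_eog)
    for (ev in evs) {
      if (ev$target == "eeg") ev_eeg <- ev_eeg + render_event(ev, profile$fs_eeg, L_eeg)
      else if (profile$eog_channels > 0) ev_eog <- ev_eog + render_event(ev, profile$fs_eog, L_eog)
    }

    drift_eeg <- if ("drift" %in% components) drift_signal(subject, t_eeg) else 0
    drift_eog <- if ("drift" %in% components) drift_signal(subject, t_eog) else 0

    make_channel <- function(L, fs, base, drift) {
      x <- base + drift
      if ("background" %in% components) x <- x + colored_noise(L, sp$background_exponent, background_rms)
      if ("noise" %in% components && subject$noise_sd > 0) {
        x <- x + stats::rnorm(L, sd = subject$noise_sd)
      }
      subject$gain * x
    }

    eeg <- matrix(0, profile$eeg_channels, L_eeg)
    for (ch in seq_len(profile$eeg_channels)) {
      eeg[ch, ] <- make_channel(L_eeg, profile$fs_eeg, osc_eeg + ev_eeg, drift_eeg)
    }
    eog <- NULL
    if (profile$eog_channels > 0) {
      eog <- matrix(0, profile$eog_channels, L_eog)
      for (ch in seq_len(profile$eog_channels)) {
        # opposite polarity of ocular bursts on the second EOG lead
        pol <- if (ch == 2L && stage == "REM") -1 else 1
        eog[ch, ] <- make_channel(L_eog, profile$fs_eog, pol * ev_eog + osc_leak, drift_eog)
      }
    }
    list(eeg = eeg, eog = eog)
  })
}

#' Default hypnogram transition matrix
#'
#' Row-stochastic 5x5 matrix over (W, N1, N2, N3, REM) with self-transition
#' probability 0.85 and off-diagonal mass following gross sleep architecture
#' (W feeds N1, N1 feeds N2, N2 exchanges with N3 and REM). Its stationary
#' distribution is imbalanced (N2-heavy, N3/REM minority), which is what
#' makes macro-F1 and overall accuracy diverge downstream.
#'
#' @param self self-transition probability.
#' @return 5x5 row-stochastic matrix with stage dimnames.
#' @export
default_transition_matrix <- function(self = 0.85) {
  r <- 1 - self
  P <- rbind(
    W   = c(self, 12, 1, 0, 2) ,
    N1  = c(3, 0, 10, 0, 2),
    N2  = c(1, 5, 0, 7, 2),
    N3  = c(1, 1, 13, 0, 0),
    REM = c(5, 5, 5, 0, 0))
  for (i in 1:5) {
    off <- P[i, ]
    off[i] <- 0
    off <- off / sum(off) * r
    off[i] <- self
    P[i, ] <- off
  }
  dimnames(P) <- list(STAGES, STAGES)
  P
}

#' Generate a hypnogram-like stage sequence
#'
#' Simulates a first-order Markov chain over the five stages.
#'
#' @param n_epochs sequence length.
#' @param transition 5x5 row-stochastic matrix (rows sum to 1 within 1e-9).
#' @param seed optional seed.
#' @param start starting stage (name or code); sleep recordings start awake,
#'   so the default is `"W"`.
#' @return integer vector of stage codes 0..4.
#' @export
generate_hypnogram <- function(n_epochs, transition = default_transition_matrix(),
                               seed = NULL, start = "W") {
  stopifnot(n_epochs >= 1)
  if (!is.matrix(transition) || any(dim(transition) != 5L)) {
    stopf("transition must be a 5x5 matrix")
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9)) {
    stopf("transition matrix rows must be non-negative and sum to 1 (within 1e-9)")
  }
  s0 <- if (is.character(start)) stage_code(start) else as.integer(start)
  with_seed(seed, {
    out <- integer(n_epochs)
    cur <- s0
    out[1L] <- cur
    if (n_epochs > 1L) {
      for (i in 2:n_epochs) {
        cur <- sample.int(5L, 1L, prob = transition[cur + 1L, ]) - 1L
        out[i] <- cur
      }
    }
    out
  })
}

#' Generate one subject's recording
#'
#' Concatenates stage-conditioned epochs along time (drift continuous across
#' the recording) into a raw [recording()] plus its stage labels.
#'
#' @param profile a [dataset_profile()].
#' @param subject a [subject_params()].
#' @param labels integer stage codes for the consecutive epochs.
#' @param seed seed for the signal stream.
#' @param profiles stage profile set.
#' @param components see [generate_epoch()].
#' @return list with `recording` and `labels`.
#' @export
generate_subject_recording <- function(profile, subject, labels, seed = NULL,
                                       profiles = stage_profiles(),
                                       components = c("background", "oscillations",
                                                      "events", "noise", "drift")) {
  labels <- check_labels(labels)
  with_seed(seed, {
    n <- length(labels)
    eeg <- matrix(0, profile$eeg_channels, n * profile$samples_eeg)
    eog <- if (profile$eog_channels > 0) matrix(0, profile$eog_channels, n * profile$samples_eog)
    for (i in seq_len(n)) {
      ep <- generate_epoch(labels[i], profile, subject, seed = NULL,
                           t_offset = (i - 1) * profile$epoch_s,
                           components = components, profiles = profiles)
      eeg[, (i - 1L) * profile$samples_eeg + seq_len(profile$samples_eeg)] <- ep$eeg
      if (!is.null(eog)) {
        eog[, (i - 1L) * profile$samples_eog + seq_len(profile$samples_eog)] <- ep$eog
      }
    }
    list(recording = recording(eeg = eeg, eog = eog, fs_eeg = profile$fs_eeg,
                               fs_eog = profile$fs_eog, subject_id = subject$id),
         labels = labels)
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` subjects (gain, drift and noise from
#' [subject_param_ranges()]), simulates a hypnogram per subject, renders the
#' signals and packs everything into an [epoch_dataset()]. With
#' `preprocess = TRUE` each subject's recording is passed through the
#' standard pipeline (detrend, per-recording z-score, segmentation) before
#' packing, which is the form the network consumes.
#'
#' @param n_subjects,epochs_per_subject cohort dimensions.
#' @param profile a [dataset_profile()].
#' @param imbalance `NULL` (default Markov architecture), a 5x5 transition
#'   matrix, or a length-5 stage-frequency vector (epochs drawn i.i.d.).
#' @param master_seed seed from which all per-subject seeds derive.
#' @param preprocess run the preprocessing pipeline per recording.
#' @param profiles stage profile set (see [stage_profiles()] for planting
#'   distribution shifts).
#' @param ranges subject parameter ranges.
#' @param subjects optional list of fixed [subject_params()] overriding the
#'   random draw (length `n_subjects`).
#' @param start_subject_id first subject id.
#' @return an [epoch_dataset()].
#' @export
generate_cohort <- function(n_subjects, epochs_per_subject,
                            profile = dataset_profile("sleep_edf"),
                            imbalance = NULL, master_seed = 1L,
                            preprocess = FALSE, profiles = stage_profiles(),
                            ranges = subject_param_ranges(),
                            subjects = NULL, start_subject_id = 1L) {
  stopifnot(n_subjects >= 1, epochs_per_subject >= 1)
  sets <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sid <- start_subject_id + s - 1L
    sp <- if (!is.null(subjects)) subjects[[s]] else {
      draw_subject_params(ranges, derive_seed(master_seed, 101L, sid), id = sid)
    }
    labels <- if (is.numeric(imbalance) && !is.matrix(imbalance)) {
      stopifnot(length(imbalance) == 5L)
      with_seed(derive_seed(master_seed, 202L, sid),
                sample(0:4, epochs_per_subject, replace = TRUE,
                       prob = imbalance / sum(imbalance)))
    } else {
      generate_hypnogram(epochs_per_subject,
                         transition = if (is.matrix(imbalance)) imbalance else default_transition_matrix(),
                         seed = derive_seed(master_seed, 202L, sid))
    }
    gen <- generate_subject_recording(profile, sp, labels,
                                      seed = derive_seed(master_seed, 303L, sid),
                                      profiles = profiles)
    rec <- gen$recording
    if (preprocess) rec <- preprocess_recording(rec)
    ds <- segment_epochs(rec, epoch_s = profile$epoch_s, profile = profile)
    ds$labels <- labels[seq_len(n_epochs(ds))]
    sets[[s]] <- ds
  }
  out <- do.call(dataset_rbind, sets)
  out$profile <- profile
  out
}
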