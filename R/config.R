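#' Dataset profiles
#'
#' A profile fixes the channel layout and sampling rates of a polysomnography
#' montage. Three presets mirror common public cohorts: `sleep_edf`
#' (2 EEG + 1 EOG, all at 100 Hz), `shhs` (2 EEG at 125 Hz + 2 EOG at 50 Hz,
#' deliberately mixed-rate so the multirate harmonization path is exercised)
#' and `hsp` (6 EEG + 2 EOG at 200 Hz, microvolt units). `custom` profiles
#' are free-form and are used to scale tests down.
#'
#' @param name one of `"sleep_edf"`, `"shhs"`, `"hsp"`, `"custom"`.
#' @param eeg_channels,eog_channels channel counts (custom only).
#' @param fs_eeg,fs_eog sampling rates in Hz (custom only).
#' @param epoch_s epoch length in seconds; sleep scoring uses 30 s.
#' @return an object of class `dataset_profile`.
#' @examples
#' dataset_profile("sleep_edf")
#' dataset_profile("custom", eeg_channels = 2, eog_channels = 1,
#'                 fs_eeg = 64, fs_eog = 64)
#' @export
dataset_profile <- function(name = c("sleep_edf", "shhs", "hsp", "custom"),
                            eeg_channels = NULL, eog_channels = NULL,
                            fs_eeg = NULL, fs_eog = NULL, epoch_s = 30) {
  name <- match.arg(name)
  preset <- switch(name,
    sleep_edf = list(eeg_channels = 2L, eog_channels = 1L, fs_eeg = 100, fs_eog = 100),
    shhs      = list(eeg_channels = 2L, eog_channels = 2L, fs_eeg = 125, fs_eog = 50),
    hsp       = list(eeg_channels = 6L, eog_channels = 2L, fs_eeg = 200, fs_eog = 200),
    custom    = list(eeg_channels = eeg_channels, eog_channels = eog_channels,
                     fs_eeg = fs_eeg, fs_eog = fs_eog))
  if (name == "custom") {
    if (is.null(preset$eeg_channels) || is.null(preset$fs_eeg)) {
      stopf("custom profile requires eeg_channels and fs_eeg")
    }
    preset$eog_channels <- preset$eog_channels %||% 0L
    preset$fs_eog <- preset$fs_eog %||% preset$fs_eeg
  }
  p <- c(list(name = name, epoch_s = epoch_s), preset)
  if (abs(p$fs_eeg * epoch_s - round(p$fs_eeg * epoch_s)) > 1e-9 ||
      abs(p$fs_eog * epoch_s - round(p$fs_eog * epoch_s)) > 1e-9) {
    stopf("epoch_s x fs must be an integer sample count")
  }
  p$samples_eeg <- as.integer(round(p$fs_eeg * epoch_s))
  p$samples_eog <- as.integer(round(p$fs_eog * epoch_s))
  structure(p, class = "dataset_profile")
}

#' @export
print.dataset_profile <- function(x, ...) {
  cat(sprintf("<dataset_profile %s: %d EEG @ %g Hz, %d EOG @ %g Hz, %g s epochs>\n",
              x$name, x$eeg_channels, x$fs_eeg, x$eog_channels, x$fs_eog, x$epoch_s))
  invisible(x)
}

#' Adaptive kernel size for efficient channel attention
#'
#' The cross-channel 1-D convolution in the ECA submodule uses a kernel whose
#' size grows with the (log of the) channel count:
#' `t = floor((log2(C) + b) / gamma)`, rounded up to the nearest odd integer.
#' With the standard constants `gamma = 2`, `b = 1` this yields k = 7 at
#' C = 2048 (the default fused width) and k = 5 at C = 128.
#'
#' @param n_channels channel count of the attended feature map.
#' @param gamma,b constants of the adaptive rule.
#' @return odd integer kernel size.
#' @export
eca_kernel_size <- function(n_channels, gamma = 2, b = 1) {
  stopifnot(n_channels >= 1)
  t <- floor((log2(n_channels) + b) / gamma)
  k <- if (t %% 2 == 1) t else t + 1
  as.integer(max(k, 1L))
}

conv_out_len <- function(L, k, s, p) (L + 2L * p - k) %/% s + 1L

#' Temporal length after the backbone
#'
#' Composes the output-length formula `floor((in + 2p - k)/s) + 1` across the
#' stem convolution (k=7, s=2, p=3), the stem max-pool (k=3, s=2, p=1) and
#' the three stride-2 stage entries (k=3, s=2, p=1). Equals `L/32` exactly
#' whenever `L` is a multiple of 32; both backbones share the schedule, so
#' EEG and EOG feature maps always align in time.
#'
#' @param L input samples per epoch.
#' @return integer temporal length of stage-4 feature maps.
#' @examples
#' temporal_length(3000) # 94
#' temporal_length(3200) # 100
#' @export
temporal_length <- function(L) {
  L <- as.integer(L)
  if (L < 32L) stopf("input length %d below the minimum of 32 samples", L)
  t <- conv_out_len(L, 7L, 2L, 3L)
  t <- conv_out_len(t, 3L, 2L, 1L)
  for (i in 1:3) t <- conv_out_len(t, 3L, 2L, 1L)
  if (t < 1L) stopf("input length %d collapses to an empty feature map", L)
  t
}

#' Model configuration
#'
#' Hyper-parameters of the fusion network. Defaults give the full-size
#' architecture: a bottleneck residual EEG branch with stage widths
#' 256/512/1024/2048 (block counts 3/4/6/3, expansion 4), a lighter
#' basic-block EOG branch with widths 64/128/256/512 (2/2/2/2), a shared
#' 1024-d embedding, a 2048-d fused representation, a temporal-attention
#' bottleneck of reduction 8 (2048 -> 256 -> 2048) and an adaptive ECA kernel
#' (7 taps at width 2048). `width_multiplier` scales every width jointly for
#' cheap test-size models.
#'
#' The ablation switches select the standard component study variants:
#' `use_eeg`/`use_eog` drop a branch (methods 1/2), `use_fusion = FALSE`
#' replaces cross-channel gating by plain concatenation (weights identically
#' one) and `use_gtca = FALSE` bypasses the gated temporal-channel attention
#' block (method 3 = both off, method 4 = fusion only, method 5 = all on).
#'
#' @param eeg_channels,eog_channels input channel counts (from the profile).
#' @param width_multiplier joint width scale; all scaled widths must stay
#'   positive integers (1/16 is the standard tiny test size).
#' @param embed_dim shared embedding width of both branch projections.
#' @param stem_width stem output channels.
#' @param eeg_stage_widths,eog_stage_widths per-stage output widths.
#' @param eeg_block_counts,eog_block_counts residual blocks per stage.
#' @param ta_reduction bottleneck reduction of the temporal attention.
#' @param fusion_reduction channel reduction inside the fusion pathways
#'   (1 = none, matching the printed layer shapes).
#' @param eca_kernel ECA kernel; `NULL` applies the adaptive rule.
#' @param eca_residual_add if `TRUE` the ECA output is added rather than
#'   multiplied (an alternative reading of the block's layer table).
#' @param n_classes number of sleep stages (5).
#' @param use_eeg,use_eog,use_fusion,use_gtca ablation switches.
#' @return an object of class `model_config`.
#' @export
model_config <- function(eeg_channels = 2L, eog_channels = 1L,
                         width_multiplier = 1,
                         embed_dim = 1024L, stem_width = 64L,
                         eeg_stage_widths = c(256L, 512L, 1024L, 2048L),
                         eog_stage_widths = c(64L, 128L, 256L, 512L),
                         eeg_block_counts = c(3L, 4L, 6L, 3L),
                         eog_block_counts = c(2L, 2L, 2L, 2L),
                         ta_reduction = 8L, fusion_reduction = 1L,
                         eca_kernel = NULL, eca_residual_add = FALSE,
                         n_classes = 5L,
                         use_eeg = TRUE, use_eog = TRUE,
                         use_fusion = TRUE, use_gtca = TRUE) {
  scale_w <- function(w) {
    s <- w * width_multiplier
    if (any(abs(s - round(s)) > 1e-9) || any(round(s) < 1)) {
      stopf("width_multiplier %g does not yield positive integer widths", width_multiplier)
    }
    as.integer(round(s))
  }
  cfg <- list(
    eeg_channels = as.integer(eeg_channels),
    eog_channels = as.integer(eog_channels),
    width_multiplier = width_multiplier,
    stem_width = scale_w(stem_width),
    embed_dim = scale_w(embed_dim),
    eeg_stage_widths = scale_w(eeg_stage_widths),
    eog_stage_widths = scale_w(eog_stage_widths),
    eeg_block_counts = as.integer(eeg_block_counts),
    eog_block_counts = as.integer(eog_block_counts),
    ta_reduction = as.integer(ta_reduction),
    fusion_reduction = as.integer(fusion_reduction),
    eca_residual_add = isTRUE(eca_residual_add),
    n_classes = as.integer(n_classes),
    use_eeg = isTRUE(use_eeg), use_eog = isTRUE(use_eog),
    use_fusion = isTRUE(use_fusion), use_gtca = isTRUE(use_gtca)
  )
  if (!cfg$use_eeg && !cfg$use_eog) stopf("at least one modality branch must be enabled")
  cfg$fused_dim <- if (cfg$use_eeg && cfg$use_eog) 2L * cfg$embed_dim else cfg$embed_dim
  if (any(cfg$eeg_stage_widths %% 4L != 0L)) {
    stopf("EEG stage widths must be divisible by the bottleneck expansion (4)")
  }
  if (cfg$use_gtca) {
    if (cfg$fused_dim %% cfg$ta_reduction != 0L) {
      stopf("fused width %d not divisible by ta_reduction %d", cfg$fused_dim, cfg$ta_reduction)
    }
    cfg$ta_bottleneck <- cfg$fused_dim %/% cfg$ta_reduction
  }
  if (cfg$embed_dim %% cfg$fusion_reduction != 0L) {
    stopf("embed_dim %d not divisible by fusion_reduction %d", cfg$embed_dim, cfg$fusion_reduction)
  }
  cfg$fusion_hidden <- cfg$embed_dim %/% cfg$fusion_reduction
  cfg$eca_kernel <- if (is.null(eca_kernel)) eca_kernel_size(cfg$fused_dim) else as.integer(eca_kernel)
  if (cfg$eca_kernel %% 2L != 1L) stopf("eca_kernel must be odd, got %d", cfg$eca_kernel)
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<model_config: EEG %dch %s | EOG %dch %s | embed %d | fused %d | ",
    "ECA k=%d | fusion=%s gtca=%s>\n"),
    x$eeg_channels, paste(x$eeg_stage_widths, collapse = "/"),
    x$eog_channels, paste(x$eog_stage_widths, collapse = "/"),
    x$embed_dim, x$fused_dim, x$eca_kernel,
    x$use_fusion, x$use_gtca))
  invisible(x)
}

#' Ablation presets
#'
#' Returns the configuration for one of the five standard component-study
#' variants: 1 = EEG branch only, 2 = EOG branch only, 3 = both branches with
#' plain concatenation, 4 = method 3 plus the cross-channel fusion module,
#' 5 = the complete network (fusion plus gated temporal-channel attention).
#'
#' @param method integer 1..5.
#' @param ... passed on to [model_config()].
#' @return a `model_config`.
#' @export
ablation_config <- function(method, ...) {
  stopifnot(method %in% 1:5)
  switch(method,
    model_config(..., use_eog = FALSE, use_fusion = FALSE, use_gtca = FALSE),
    model_config(..., use_eeg = FALSE, use_fusion = FALSE, use_gtca = FALSE),
    model_config(..., use_fusion = FALSE, use_gtca = FALSE),
    model_config(..., use_gtca = FALSE),
    model_config(...))
}

#' Serialize / restore a model configuration
#'
#' @param config a `model_config`.
#' @param path file path for the JSON document.
#' @return `config_write` returns `path` invisibly; `config_read` the config.
#' @export
config_write <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # stored widths are already scaled, so the multiplier is folded back to 1
  model_config(eeg_channels = raw$eeg_channels, eog_channels = raw$eog_channels,
               width_multiplier = 1,
               embed_dim = raw$embed_dim, stem_width = raw$stem_width,
               eeg_stage_widths = raw$eeg_stage_widths,
               eog_stage_widths = raw$eog_stage_widths,
               eeg_block_counts = raw$eeg_block_counts,
               eog_block_counts = raw$eog_block_counts,
               ta_reduction = raw$ta_reduction,
               fusion_reduction = raw$fusion_reduction,
               eca_kernel = raw$eca_kernel,
               eca_residual_add = raw$eca_residual_add,
               n_classes = raw$n_classes,
               use_eeg = raw$use_eeg, use_eog = raw$use_eog,
               use_fusion = raw$use_fusion, use_gtca = raw$use_gtca)
}
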