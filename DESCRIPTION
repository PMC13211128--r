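Package: sleepfuse
Title: Multimodal EEG-EOG Sleep Staging with Cross-Channel Fusion and
    Gated Temporal-Channel Attention
Version: 0.1.0
Authors@R:
    person("PSG", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for five-class sleep staging (W, N1, N2, N3, REM) from
    30-second polysomnography epochs. Implements modality-specific 1-D
    residual backbones for EEG and EOG, a bidirectional cross-channel
    attention fusion module, a gated temporal-channel attention block with
    efficient channel attention, and a linear classification head, together
    with the surrounding machinery: linear detrending and per-recording
    z-score preprocessing, epoch segmentation, multirate harmonization,
    stratified cross-validation training with Adam, confusion-matrix metrics
    (overall accuracy, Cohen's kappa, macro-F1), per-epoch EEG-EOG Spearman
    correlation with a Kruskal-Wallis omnibus test, Grad-CAM style saliency
    for 1-D signals, and head-only subject adaptation. A stage-conditioned
    synthetic polysomnography generator provides reproducible test data so
    the whole pipeline runs without any clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
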