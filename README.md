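# sleepfuse

Multimodal EEG–EOG sleep staging in R: modality-specific 1-D residual
backbones, bidirectional cross-channel attention fusion, a gated
temporal-channel attention block, and everything around the network —
preprocessing, stratified cross-validation training, confusion-matrix
metrics, stage-wise correlation statistics, Grad-CAM saliency for 1-D
signals, and head-only subject adaptation. A stage-conditioned synthetic
polysomnography generator makes the whole pipeline runnable and testable
without any clinical recordings.

## Who this is for

Researchers in computational sleep medicine and biosignal machine learning
who want a transparent, fully-tested reference implementation of an
interactive fusion architecture for five-class sleep staging (W, N1, N2,
N3, REM) from 30-second epochs — including the analysis machinery that
usually lives in scattered scripts: ablation variants, branch probes around
the fusion point, interpretability maps and per-subject adaptation. The
network and its backward pass are implemented from first principles (R +
RcppArmadillo kernels), so every layer is inspectable and every gradient is
finite-difference-verified.

## The model

Raw epochs `X_EEG ∈ R^(C_e×L)`, `X_EOG ∈ R^(C_o×L)` pass through:

1. **Backbones** — a shared stem `MaxPool(ReLU(BN(Conv k=7,s=2)))`, then a
   bottleneck residual network for EEG (stages 256/512/1024/2048, blocks
   3/4/6/3, expansion 4) and a lighter basic-block network for EOG
   (64/128/256/512, 2/2/2/2), both ending at temporal length `L/32` and
   projected to a shared 1024-d embedding `f_EEG`, `f_EOG`.
2. **Cross-channel fusion** — each modality is rescaled per channel by a
   sigmoid gate computed from the *other* modality's time-pooled
   descriptor: `f̄_EEG = f_EEG ⊗ σ(W₂ ReLU(W₁ avg_t f_EOG))` (and
   symmetrically); the fused map is `[f̄_EEG; f̄_EOG] ∈ R^(2048×L/32)`.
3. **Gated temporal-channel attention** — squeeze-excitation temporal
   weights `a` with bottleneck 2048→256→2048 and residual batch norm;
   a per-channel-per-timestep gate `g` mixing original and enhanced
   features; efficient channel attention (ECA) with the adaptive kernel
   `k = odd⌊(log₂C+1)/2⌋` (= 7 at C = 2048) applied across the channel
   axis of the pooled descriptor.
4. **Head** — global average pooling, one linear layer, softmax over the
   five stages; plain cross-entropy for training.

Evaluation follows the standard protocol: stratified epoch-level 5-fold
cross-validation, Adam (lr 1e-4, weight decay 1e-4, 100 epochs, batch 32),
best-validation-accuracy checkpointing, and OA / Cohen's κ / macro-F1 from
the pooled confusion matrix.

## Worked example

```r
library(sleepfuse)

# 1. simulate a small preprocessed cohort (2 subjects x 100 epochs, 32 Hz)
profile <- dataset_profile("custom", eeg_channels = 2, eog_channels = 1,
                           fs_eeg = 32, fs_eog = 32)
cohort <- generate_cohort(n_subjects = 2, epochs_per_subject = 100,
                          profile = profile, imbalance = rep(1, 5),
                          master_seed = 5, preprocess = TRUE)
cohort
#> <epoch_dataset: 200 epochs, 2 subjects, profile custom>
#>   eeg: 200x2x960 @ 32 Hz
#>   eog: 200x1x960 @ 32 Hz
#>   labels: W=28 N1=42 N2=37 N3=50 REM=43
#>   preprocessing: detrend -> zscore -> segment

# 2. train a test-size network (width multiplier 1/16)
cfg <- model_config(eeg_channels = 2, eog_channels = 1, width_multiplier = 1/16)
net <- build_model(cfg, seed = 1)
tc <- train_config(lr = 1e-3, weight_decay = 1e-4, epochs = 10,
                   batch_size = 16, val_fraction = 0.2, seed = 1)
history <- train_model(net, cohort, config = tc)
#> best epoch: 8 (validation accuracy 1.00)

# 3. evaluate on the full cohort
pred <- model_predict(net, cohort)
metrics_report(cohort$labels, pred$labels)
#> OA 97.00%  kappa 0.9621  MF1 0.9610
#>   class precision recall    f1 support
#> 1     W     1.000  0.786 0.880      28
#> 2    N1     1.000  1.000 1.000      42
#> 3    N2     0.881  1.000 0.937      37
#> 4    N3     1.000  1.000 1.000      50
#> 5   REM     0.977  1.000 0.989      43

# 4. stage-wise EEG-EOG Spearman correlation with omnibus test
stagewise_correlation(cohort)
#> Per-stage median rho (|rho|):
#>   W    +0.0147 (0.0629)  n=28
#>   N1   +0.0129 (0.0369)  n=42
#>   N2   +0.0438 (0.0765)  n=37
#>   N3   +0.8750 (0.8750)  n=50
#>   REM  +0.0292 (0.0484)  n=43
#> Kruskal-Wallis H = 114.21, p = 9.21e-24
```

The numbers mean: the tiny model separates the five synthetic stages almost
perfectly (OA 97%, κ 0.96 — chance-corrected agreement near ceiling; the
only confusions are W epochs read as N2); and the correlation analysis
recovers the one cross-modal link the generator plants — N3 slow waves
leaking into the ocular leads (median |ρ| 0.88 in N3, ≈0 elsewhere; the
omnibus test confirms stage-dependent correlation structure). Synthetic
accuracies validate the implementation, not clinical performance — see the
methods vignette (`vignettes/sleepfuse-methods.Rmd`).

Ablation presets (`ablation_config(1:5)`), branch probes
(`branch_probe()`), saliency maps (`gradcam()`) and subject adaptation
(`external_validate()`, `finetune_head()`) are exercised the same way; the
command-line surface in `inst/cli.R` wraps the main verbs
(`simulate`, `harmonize`, `train`, `evaluate`, `correlate`, `gradcam`,
`adapt`), writing a JSON run manifest next to every output.

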