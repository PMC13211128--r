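---
title: "Multimodal sleep staging: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal sleep staging: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sleepfuse)
```

## The problem

Sleep staging assigns each 30-second polysomnography epoch to one of five
stages — Wake (W), N1, N2, N3, REM — from the raw electrophysiology. EEG
carries most of the stage-defining oscillations (alpha in quiet wake, theta
at sleep onset, spindles and K-complexes in N2, high-amplitude delta in N3),
while the electrooculogram (EOG) is decisive where EEG is ambiguous: rapid
eye movements mark REM, slow rolling movements mark sleep onset, blinks mark
wake. `sleepfuse` implements a single-epoch classifier that learns each
modality separately and then lets the two streams modulate one another.

## The model

Inputs are channel-first arrays $X_{\mathrm{EEG}} \in \mathbb{R}^{C_e \times L}$,
$X_{\mathrm{EOG}} \in \mathbb{R}^{C_o \times L}$ at a common temporal length
$L$ (see *Multirate inputs* below). Four parts:

**1. Modality-specific residual backbones.** Each branch starts with an
identical stem, `MaxPool(ReLU(BN(Conv(k=7, s=2, p=3))))`, to 64 channels at
$L/4$. The EEG branch then stacks bottleneck residual units
(`1x1 -> 3x1 -> 1x1`, expansion 4) in four stages of 3/4/6/3 blocks with
widths 256/512/1024/2048; the EOG branch — smoother, spectrally simpler —
uses lighter basic blocks (`3x1 -> 3x1`), 2/2/2/2 blocks at widths
64/128/256/512. Stages 2–4 open with a stride-2 unit; both branches end at
temporal length $T = L/32$ (exactly when $32 \mid L$; otherwise
`temporal_length()` gives the floor-composition value). A final 1×1
convolution projects both branches into a shared 1024-dimensional embedding,
$f_{\mathrm{EEG}}, f_{\mathrm{EOG}} \in \mathbb{R}^{1024 \times T}$.

**2. Bidirectional cross-channel fusion.** Each modality is rescaled
per-channel by a gate computed from the *other* modality's time-pooled
descriptor:
$$w_{\mathrm{EOG}\to\mathrm{EEG}} = \sigma(W_2\,\rho(W_1\, \bar f_{\mathrm{EOG}})), \qquad
  \bar f_{\mathrm{EEG}} = f_{\mathrm{EEG}} \otimes w_{\mathrm{EOG}\to\mathrm{EEG}},$$
(and symmetrically), where $\rho$ is ReLU, $\sigma$ the logistic function
and $\otimes$ broadcasts over time. The fused map is the channel
concatenation $[\bar f_{\mathrm{EEG}}; \bar f_{\mathrm{EOG}}] \in
\mathbb{R}^{2048 \times T}$, EEG first.

**3. Gated temporal-channel attention.** Three stages refine the fused map
$f$: (i) a squeeze-excitation-style temporal attention
$a = \sigma(W_4\,\rho(W_3\,\bar f))$ with bottleneck 2048→256→2048 and
residual normalization $f_{\mathrm{temp}} = \mathrm{BN}(f \otimes a + f)$;
(ii) a per-channel-per-timestep gate $g = \sigma(\mathrm{Conv}_{1\times1}(f))$
mixing $f_{\mathrm{gate}} = g \otimes f + (1-g) \otimes f_{\mathrm{temp}}$;
(iii) efficient channel attention: the time-pooled descriptor is convolved
*across the channel axis* with a small kernel and squashed,
$F = f_{\mathrm{gate}} \otimes \sigma(\mathrm{Conv}_{1\times k}(\mathrm{avg}_t f_{\mathrm{gate}}))$.
The kernel follows the adaptive rule
$k = \mathrm{odd}\lfloor(\log_2 C + 1)/2\rfloor$, giving $k = 7$ at
$C = 2048$ — `eca_kernel_size()` reproduces this and the config validator
asserts it.

**4. Head.** Global average pooling over time, one linear layer, softmax
over the five stages; training minimizes plain cross-entropy (no class
weighting — imbalance is reported, not corrected).

### Design choices where the architecture description was open

* **"Shared" final projection.** The two branches end at different widths
  (2048 vs 512), so one weight matrix cannot literally serve both; we use
  two projections sharing only the output dimension.
* **Fusion pathway reduction.** The printed layer table shows
  1024→1024→1024, i.e. no channel reduction; the default
  `fusion_reduction = 1` matches it and remains configurable.
* **ECA combination.** The block equation multiplies the ECA weights into
  the gated map while the layer table's last row reads "element-wise
  addition"; the default follows the equation (multiplication), and
  `eca_residual_add = TRUE` selects the table variant.
* **Stride placement.** In bottleneck units the stride sits on the 3×1
  convolution; shortcuts use a stride-matched 1×1 projection with BN —
  the standard residual convention consistent with the published shapes.
* **Weight sharing across fusion directions** is not stated; the two
  pathways are unshared.
* **Concatenation order** is EEG then EOG, as listed.

## Preprocessing

Exactly three steps, in order: (1) first-order least-squares detrending per
channel over the *whole recording* (the drift it removes — electrode
impedance, perspiration — lives at recording scale, hence whole-recording
rather than per-epoch granularity); (2) z-score per channel with mean and SD
computed per recording, never per epoch; (3) segmentation into contiguous,
non-overlapping 30-s windows from sample zero, trailing remainder dropped.
No filtering, no artifact rejection, no epoch exclusion — the
`preprocessing_flags` field records the applied steps and the tests assert
nothing else ever appears. Zero-variance channels cannot be standardized
and become all-zeros with a warning, keeping batch shapes valid.

**Multirate inputs.** One supported montage records EEG at 125 Hz and EOG at
50 Hz; the published description never states how the two are reconciled,
but the fused concatenation requires equal temporal length after the /32
downsampling. `harmonize_rates()` therefore resamples (by default upsamples
the slower modality to the faster rate) with rational-ratio polyphase
resampling: zero-stuffing, a Hamming-windowed sinc low-pass at the tighter
Nyquist, decimation, reflection-padded edges. Bandlimited tones survive with
correlation > 0.999 and in-band energy error < 1%.

## Training protocol

Adam with learning rate 1e-4 and L2 weight decay 1e-4 (added to the raw
gradient), 100 epochs, batch size 32, samples reshuffled every epoch; the
hyper-parameter grid is lr ∈ {1e-3, 1e-4, 1e-5} × wd ∈ {1e-5, 1e-4, 1e-3}.
Evaluation uses stratified 5-fold cross-validation at the epoch level
(subject-aware folds are available as an extension flag). The protocol
defines train and test folds only; checkpoint selection needs validation
data, so we split a stratified 10% off the training fold — the
smallest-departure reading that enables "best validation accuracy"
checkpointing without ever touching the test fold. Ties break toward the
earliest epoch; selection is a pure argmax over the logged history. No
learning-rate schedule and no early stopping. A trailing mini-batch of size
one is dropped (its batch statistics are undefined).

## Metrics

From the 5×5 confusion matrix (rows = true, columns = predicted, order W,
N1, N2, N3, REM): overall accuracy $\mathrm{OA} = 100 \cdot \mathrm{tr}(M)/N$;
Cohen's $\kappa = (P_0 - P_e)/(1 - P_e)$ with the standard multiclass chance
agreement $P_e = \sum_c (r_c/N)(c_c/N)$; macro-F1 as the unweighted mean of
per-class F1 (reported as a fraction). Two published formulas required a
decision: the printed OA formula sums $(TP_c + TN_c)/N$ over classes, which
exceeds 100% for any multiclass matrix, so we implement the accompanying
prose definition (proportion of correctly predicted samples); the printed
$P_e$ is the two-class binary form, and the multiclass marginal product we
use reduces to it at $C = 2$. A class absent from both truth and prediction
contributes F1 = 0 with a warning — conservative, and the reason macro-F1
sits below OA on imbalanced folds.

## The synthetic cohort generator

No clinical data ships with the package; every test runs on
`generate_cohort()`. The generator emulates exactly the structure the
pipeline assumes, and nothing more:

* **Background**: 1/f (β = 1) noise at 10 µV RMS plus white sensor noise —
  the simplest background that makes stages separable while keeping
  detrending and normalization non-trivial. All amplitudes are in µV.
* **Stage signatures** (EEG): 8–12 Hz alpha in W (20 µV), 4–7 Hz theta in
  N1 (20 µV), 12–14 Hz spindle bursts of 0.5–1.5 s plus one biphasic
  K-complex over a weak theta floor in N2, 0.5–2 Hz delta at 60 µV in N3,
  and a low 6 µV theta floor in REM. EOG: blinks in W, slow rolling
  movements in N1, and 5–9 sharp bursts in REM placed with opposite
  polarity on the two EOG leads when the montage has two. Amplitudes were
  chosen once so that each stage's designated band shows the largest
  relative power increase over the background (Welch-periodogram oracle,
  ≥95% of epochs) with a comfortable margin; they were not revisited after
  the tests were frozen.
* **A planted cross-modal link**: N3 slow waves leak into the EOG at
  coefficient 0.5, mimicking frontal slow-wave contamination of ocular
  leads. This single mechanism grounds the stage-wise correlation analysis
  (N3 shows the largest |ρ|) — no other stage shares signal across
  modalities.
* **Subjects**: gain U(0.5, 2), linear drift U(−0.05, 0.05) µV/s, a slow
  sinusoidal drift wave (≤20 µV, 1–5 min period), noise SD U(1, 3) µV.
  Identical seeds give bit-identical subjects.
* **Hypnograms**: a first-order Markov chain; the default matrix uses 0.85
  self-transitions with off-diagonal mass following gross sleep
  architecture, so the stationary distribution is imbalanced and macro-F1
  diverges from OA. A stage-frequency vector may replace the chain.

What the generator does **not** emulate: volume conduction and realistic
spatial covariance, artifacts beyond gain/drift/noise, spectral
nonstationarity within a stage, or inter-epoch context. A green test
therefore establishes that the implementation is faithful and the pipeline
end-to-end coherent — not that the architecture would reach any particular
accuracy on clinical recordings.

## Scaled test world

The acceptance suite must run on one CPU in minutes, so the training
criteria use a reduced world chosen once: a custom 32 Hz profile
(960 samples per 30-s epoch — the lowest rate whose Nyquist clears the 14 Hz
spindle band), `width_multiplier = 1/16`, cohorts of 200–1200 epochs,
learning rate 1e-3 (a grid value) with batch 16 so the variants reach
convergence within ~60–90 update steps. Structural criteria (layer shapes,
ECA kernel, bypass equivalence) run at the full default size. The ablation
ordering property compares mean test OA over three seeded runs and allows a
3-percentage-point sampling tolerance between successive variants — set
a priori from the observed fold-to-fold spread of small test splits
(~50 test epochs give 2-point OA granularity).

## Subject adaptation

External validation applies a trained model to held-out subjects, then
fine-tunes *only* the classification head on a stratified 10% of each
subject's epochs (largest-remainder rounding per class, every class with ≥2
epochs contributing at least one). The freeze contract is verified, not
trusted: backbone parameters are digested (MD5 over canonical
serialization) before and after, and adaptation never touches test epochs
(index sets are returned for audit). Because the backbone is frozen, the
head is trained on cached time-pooled features — identical mathematics,
orders of magnitude cheaper. The fine-tuning budget is not stated anywhere;
with adaptation sets of tens of samples the protocol's 1e-4 rate barely
moves the head, so the default budget is 50 full-batch epochs at 1e-3
(a grid value), all configurable. The planted distribution shift in the
acceptance test (attenuated slow-wave/spindle amplitude, boosted
light-sleep theta) emulates an atypical-subject phenotype that moves class
clusters without destroying their separability — exactly the regime where a
re-fit linear boundary can help.

## Branch probes around the interaction

"Before interaction" performance of each branch is the corresponding
single-modality pipeline trained from scratch. "After interaction" is not
defined operationally in the source description; retraining full branches
would conflate representation quality with optimization effects, so we
freeze the trained full model, extract the time-pooled *modulated* branch
features $\bar f$, and fit a linear softmax probe — measuring the
information content of each branch after cross-modal modulation.

## Grad-CAM for 1-D signals

At three tap points (EEG embedding, EOG embedding, attention-block output):
channel weights are the time-averaged gradients of the target-class logit,
the map is the ReLU-ed weighted channel sum at feature resolution
($T = L/32$), linearly interpolated back to $L$ and max-normalized; an
all-zero map is returned unnormalized and flagged. Maps from untrained
models are shape-valid but uninformative; the localization test plants
spindle/K-complex events as the only discriminative cue and requires the
saliency argmax to fall within one feature stride (1 s — the map's native
resolution) of an event window in ≥80% of epochs.

## Numerical choices

Batch norm uses biased variance for normalization, unbiased for running
statistics (momentum 0.1, ε = 1e-5); eval mode uses running statistics, so
eval-mode forward passes are bit-deterministic. Convolutions are initialized
Kaiming fan-out, BN at γ = 1, β = 0, linear layers uniform ±1/√fan-in; all
initialization is a pure function of the build seed. Adam uses β = (0.9,
0.999), ε = 1e-8, with weight decay added to the raw gradient. Max-pool
ties break toward the earliest tap. The hot kernels run in C++ with pure-R
reference implementations kept as test oracles, and every backward pass is
checked against central finite differences.

## Known limitations

Single-epoch classification only — no sequence context, although real
scorers use it. The RDS container replaces HDF5 (no binding in the
supported stack) while keeping the documented schema. EDF ingestion is
best-effort: continuous 16-bit EDF with a plain-text hypnogram sidecar
(legacy R&K codes merged into N3), not EDF+ annotations. Reported synthetic
accuracies say nothing quantitative about clinical data.
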