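---
title: "Differential-entropy EEG tensors, attention, and cross-modal distillation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(deeframe)
```

# The problem

Dimensional emotion recognition from EEG asks whether short segments of
multichannel scalp recordings can be classified as high or low valence
(or arousal), where the ground truth is the subject's own 1–9 rating of
the stimulus, binarized at the conventional threshold of 5 (a rating of
exactly 5 maps to *low*; the threshold side is a convention, fixed here
once). `deeframe` implements a complete subject-dependent pipeline for
this task — feature construction, an attention-based convolutional
recurrent classifier, and cross-modal knowledge distillation from a
facial-video network — together with a synthetic-data module that makes
every stage testable without access-restricted recordings.

# Feature construction

**Baseline removal.** Each trial carries a pre-stimulus baseline
segment. The baseline is cut into non-overlapping windows of the
analysis length, averaged elementwise per channel into a template
window, and the template is subtracted from every experimental window.
This is the dominant convention in the DEAP literature; the method is
otherwise underdetermined, and artifact/EOG rejection is out of scope.

**Windowing.** Experimental signals are segmented into non-overlapping
windows (2 s at 128 Hz for DEAP-shaped data; 0.5 s at 256 Hz with the
middle 30 s selected for MAHNOB-shaped data). Trailing samples that do
not fill a window are discarded. These shapes reproduce the familiar
counts: 22 subjects × 40 trials × 30 windows = 26,400 (1,200 per
subject) and 25 × 20 × 60 = 30,000.

**Band decomposition.** Each window is decomposed into θ (4–7 Hz),
α (8–13 Hz), β (14–30 Hz) and γ (31–50 Hz) with an order-4 Butterworth
band-pass applied forward–backward (zero phase), so band signals remain
time-aligned with the window. Zero-phase filtering doubles the
effective order; the order and the zero-phase choice are design
decisions — only the filter family is canonical.

**Differential entropy.** For a Gaussian band-limited signal the
differential entropy is the closed form

$$h = \tfrac{1}{2}\,\ln\!\left(2\pi e\,\sigma^2\right)\ \text{nats},$$

estimated per channel, band and sub-slice from the unbiased sample
variance. Natural logarithms are used throughout (the closed form is
its natural-log form); a variance floor of `1e-12` keeps the value
finite on degenerate slices rather than returning −∞.

**Topographic projection and stacking.** Per-band DE values are placed
on a sparse 9 × 9 grid at the cells of a 32-channel 10–20 montage
(shipped as an editable JSON file, 0-based row-major coordinates);
unoccupied cells are exactly zero. The window is split into `T` equal
sub-slices (default `T = 4` for 2-s windows, i.e. 0.5-s slices), giving
a `T × B × 9 × 9` tensor per window. The meaning of `T` is genuinely
open in the source material (sub-slices per window vs. windows per
trial); sub-slices within one window were chosen because they make one
tensor one classified sample, which is the only reading consistent with
the stated sample counts. The window is filtered once and then sliced —
zero-phase filtering makes this equivalent to slicing first, and far
cheaper.

# The EEG branch

Per time slice, a frequency-band gate in the style of efficient channel
attention: global average pooling reduces each band to a scalar
descriptor, a 1-D convolution across bands (kernel size from
`adaptive_kernel_size()`: nearest odd integer to
`log2(B)/2 + 1/2`, giving `k = 1` for four bands, minimum 1, ties to
the smaller odd) produces a pre-activation per band, and a sigmoid
yields weights in (0, 1) that rescale the bands. The gate's convolution
is shared across slices; activations are per-slice. Whether "normalize
the weights" means anything beyond the sigmoid is ambiguous in the
source; sigmoid alone was chosen.

With a single band (`k = 1`) the gate has one shared coefficient, so
amplification (positive coefficient) and attenuation (negative) are
equally expressive per sample — either sign lets the downstream network
exploit the class-dependent descriptor. The gate is therefore
initialised mildly amplifying (`0.25/k` per tap) rather than
random-signed: with a random start the sign of the trained gate, and
hence the ordering of the reported mean band weights, is decided by
initialisation noise rather than by the data. This matters only for
interpretability of the report; accuracy is unaffected.

The gated slices pass through four same-padded ReLU convolutions
(kernels 5×5, 4×4, 3×3, 1×1; channels 64, 128, 256, 128 at reference
width), a 2×2 stride-2 max pool (9×9 → 4×4; the source text labels this
operator Conv in one place and max pooling in the prose — the prose
wins), a flatten (4·4·128 = 2048) and a dense layer to 512. The slice
features form a `T × 512` sequence fed to a 2-layer peephole LSTM with
hidden size 128: the printed gate equations include cell-state terms in
all three gates, so the peephole variant is kept, with the standard
diagonal (elementwise) peephole parameterisation. Hidden size 128
follows the printed feature dimension, overriding a contradictory prose
statement ("hidden units set to the sample number").

Self-attention over time steps uses the additive form
`S_t = W_t · ReLU(W_1 h_t + W_2 d_t + b_1) + b_2` with the alignment
vector `d_t` a bias-free linear map of `h_t` of the same dimension (the
printed formula's parenthesisation is typographically garbled; this is
the standard additive-attention reading). Similarities `N_t = S_t' h_t`
are softmaxed (stably, max-shifted) into probabilities `P`, the hidden
states are reweighted `A_t = P_t h_t`, summed over `t` (keeping the
`P_t` weighting meaningful), and classified by a dense softmax head.
The feature sequence `V_s` used for distillation is the self-attention
output `A` — the "spatial–temporal features" tap point is not named in
the source; the attention output is the last representation before
pooling.

# The visual branch

Clips are `T` frames of 48 × 48 × 3. A per-frame CNN (two 3×3 convs of
32 and 64 channels, each followed by ReLU and a 2×2 max pool, then a
dense layer) produces `T × 512` spatial features; the internal channel
and kernel choices are design decisions — only the layer counts and the
512 output are fixed by the source. A temporal convolutional network
first projects to 128 channels, then applies two *parameter-shared*
temporal-convolution modules — one kernel-3 dilation-1 conv and two
kernel-3 dilation-2 convs, each followed by ReLU, batch-style
per-channel normalisation and dropout 0.5, plus a 1×1-conv residual
path — and a kernel-2 stride-1 average pool over time, preserving
sequence length (same padding; the TCN is non-causal since clips are
processed offline). One module spans 11 time steps (1 + 2 + 4 + 4).
A per-step dense softmax head gives `T × 2` outputs trained with
cross-entropy against the clip label at every step. Feature extraction
for distillation runs in inference mode (dropout off, running
normalisation statistics), returning the `T × 128` TCN output.

The parameter sharing forces both modules to have equal input and
output widths, which is why the 512 → 128 projection precedes the
first module rather than living inside it.

# Distillation

The student (EEG) loss is

$$L = \rho\,\mathrm{CE}(P, Y) + (1-\rho)\, w^{*}\,
\frac{1}{TF}\sum_{t,f}\left|V_t - V_s\right|,$$

with ρ = 0.8 and the L1 weight `w*` grid-searched over 0.5–1.5 in
steps of 0.1 (11 candidates; ties go to the smaller value). The printed
loss omits the absolute-value bars but names the term L1; the bars are
restored. Teacher features are extracted once and held fixed (offline
distillation). At ρ = 1 the teacher is ignored entirely and the run is
bit-identical to a no-distillation run under the same seed. Probability
logs are floored at `1e-12`. Grid search scores candidates on a
held-out validation split — the source optimised hyper-parameters on
the test set, which is methodologically unsound and deliberately not
reproduced.

Training uses Adam (the optimiser is unnamed in the source; Adam is the
field default) with the reference learning rates 1e-6 (EEG) and 1e-5
(visual), batch size 128, up to 100 epochs, and best-validation
checkpoint retention for the visual branch ("optimal model parameters
loaded at the end of each epoch" read as best-so-far checkpointing).
Evaluation is five-times-repeated stratified tenfold cross-validation
per subject (stratification is a design choice; "high" is the positive
class for precision/recall/F1), aggregated as mean ± SD across
subjects.

# The synthetic-data module

The generator is the package's study bench, not a fixture: its defaults
define the conditions under which the training-based tests run.

Each channel's background is a sum of four narrowband oscillators (one
per band, frequency uniform within the band, random phase per
channel × trial) plus `1/f` pink noise (spectral shaping of white
noise, unit variance, 30% of the background power). Oscillator
variances are calibrated analytically so the total background power
*inside* each band is equal across the four bands — the pink noise
contributes more power to some bands than others, and the oscillators
compensate. Class-1 trials have the informative band's total in-band
power on the informative channels (ten posterior electrodes by default)
raised to exactly `effect_size` times the class-0 power; an independent
Welch-style spectral estimate recovers the injected ratio within
tolerance in the tests. Baselines use the same background process with
no class signal, making baseline removal testable. Ratings are drawn
uniformly from 1–4 (low) or 6–9 (high), never 5, avoiding the
threshold boundary. Classes are balanced within subject to ±1 trial.

Two caveats documented deliberately. First, after the Butterworth
stage the per-band DE values are *not* perfectly flat across bands
(narrow bands lose oscillator power to the filter's passband ripple,
wide bands gain skirt noise): the class-0 descriptors rise mildly from
θ to γ, with β and γ within ~0.002 of each other. The γ-recovery
experiment is therefore read against β as the competing band; the
class effect, not the filter asymmetry, is what separates them.
Second, the generator's oscillator-plus-pink-noise process emulates
band structure, 1/f background, trial/baseline structure and a single
band-power class effect — it does not emulate artifacts, volume
conduction, non-stationarity, cross-channel correlation or rating
noise, so passing tests demonstrate correctness of the machinery and
directional behaviour of the method, not real-data performance.

Visual feature sequences are Gaussian `T × F` matrices whose class
means differ by `snr` (Euclidean distance, unit noise); `snr = 0` is
exactly label-independent. Frame clips show a Gaussian blob drifting
with class-dependent speed (1 vs 3 px/frame by default) and reflecting
at borders, giving the visual network a learnable motion cue.

# Numerical choices

* Variance floor `1e-12` in the DE estimator; log floor `1e-12` in
  cross-entropy.
* Softmax is max-shifted; attention probabilities sum to 1 within 1e-9.
* Max-pool ties resolve to the first (top-left) element.
* Middle-segment selection trims the extra sample from the head when
  the trimmed count is odd.
* Uniform Glorot initialisation for convolutional and dense weights,
  orthogonal for recurrent maps, zeros for biases; all seeded, and all
  generators save and restore the caller's RNG state.
* Window timestamps are half-open; grid coordinates 0-based row-major
  in files, 1-based inside R.

# Reduced-scale experiment design

All networks take configurable widths with the reference architecture
as default. The shape contracts (512 per frame/slice, `T × 128`
sequences) are asserted at reference width, where a forward pass is
cheap. The training-based experiments — band-attention recovery,
attention and distillation ablations — run a reduced-width
configuration (conv channels 8/12/16/12, dense 48, hidden 24) on small
benches, a deliberate problem-size choice so that multi-seed
experiments are practical on one CPU:

* *Recovery bench*: 2 subjects × 40 trials × 6 s, effect size 3 in γ,
  2-s windows (240 samples), 30 epochs at learning rate 2e-3, five
  seeds. The trained mean γ weight is compared against the other three
  bands.
* *Attention bench*: same shape with effect size 1.3, where accuracy is
  well off the ceiling so removing the attention modules has visible
  cost; full vs. no-attention over the same five seeds (35 epochs).
* *Distillation bench*: effect size 1.8 — enough signal that the
  student can track the teacher's structure, not so much that the
  ρ = 1 baseline saturates — with a low-noise synthetic teacher
  (`snr = 30`, hidden-width F = 24), ρ = 0.8 vs. ρ = 1 paired over
  five seeds (40 epochs).

* *Visual bench*: 120 clips of 6 frames with a strong motion contrast
  (0.5 vs. 5 px/frame), a reduced-width network (channels 8/16, dense
  64, TCN width 16, dropout off — at 90 training clips dropout only
  starves the fit), 20 epochs at learning rate 1e-3, three seeds.

The teacher sequences for the distillation bench are generated at
amplitude `scale = 0.02`. This is not cosmetic: the student feature
`V_s` is the attention output `A_t = P_t h_t`, bounded to roughly
`1/T` in magnitude by the tanh LSTM and the attention simplex, so a
unit-scale teacher is unreachable and its L1 pull degenerates to a
constant-magnitude sign gradient that only perturbs training.
Separability depends on `snr` alone, so scaling the teacher into the
student's feasible range changes nothing about its information
content. Likewise the teacher noise is kept small (`snr` large): the
per-sample noise in a teacher sequence is unpredictable from the EEG
input, so matching it is target noise; what helps the student is the
class-conditional mean structure.

The reference learning rates (1e-6/1e-5) pair with 100-epoch training
on tens of thousands of windows; at bench scale they would not move the
loss, so the benches pass explicit `epochs`/`lr` overrides, as any
caller may.

# Known limitations

* The CNN-LSTM and TCN are R implementations (BLAS-backed im2col
  convolutions with two small compiled gather/scatter kernels, explicit
  backpropagation, finite-difference-verified); they are correct but
  not framework-fast, and reference-width training at dataset scale is
  out of reach on a single CPU.
* Subject-independent transfer, artifact handling, face detection and
  pre-training on external face datasets are out of scope.
* The EDF reader handles continuous 16-bit recordings without
  annotation channels; the MAT reader handles uncompressed v5 double
  arrays.
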