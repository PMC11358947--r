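---
title: "Decoding driving attention states from EEG band power: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding driving attention states from EEG band power: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegdrive)
```

`eegdrive` classifies one-second windows of multichannel EEG into four
driving attention states — focused driving and visual, auditory and
cognitive distraction. This vignette explains the signal chain, the
models, the synthetic data the package tests itself on, and the design
choices that were genuinely open.

## The data model and preprocessing chain

A recording is a channels × samples matrix in microvolts at a known
sampling rate, with an event table marking trial onsets
(`eeg_recording()`). The offline chain (`preprocess_recording()`) is:

1. **Mastoid re-referencing.** Every channel gets
   0.5·(TP9 + TP10) subtracted sample-wise. The mastoids are kept until
   the explicit channel-selection step so the two operations remain
   independently testable.
2. **Channel selection.** From the 64-channel cap we drop the reference
   Fz, the ocular-dominated Fp1/Fp2, and the consumed mastoids
   TP9/TP10, leaving exactly 59 analysis channels in stable order. This
   is the only accounting consistent with the 59-channel feature
   matrices used throughout the models.
3. **Band-pass filtering.** 4th-order Butterworth high-pass and
   low-pass sections applied forward–backward (zero phase), 0.5–50 Hz
   offline. The filter realisation is not dictated by the science; a
   zero-phase Butterworth is standard EEG practice and preserves event
   latencies. Channels are demeaned before filtering so DC is removed
   exactly. The online preset uses 0.1–45 Hz; the two presets are kept
   as distinct named configurations rather than silently unified,
   because the offline/online band mismatch is part of the system being
   modelled.
4. **Downsampling** to 100 Hz (anti-alias Butterworth at 0.8× the
   target Nyquist, then decimation). One second of signal is exactly
   100 samples from here on.
5. **Epoching and windowing.** One epoch per valid trial with
   state-specific durations (focused/visual 5 s, cognitive 10 s,
   auditory 15 s); trials whose behavioural feedback was missed are
   excluded here, before any feature computation. Epochs are cut into
   non-overlapping 1-s windows — a D-second trial yields exactly D
   windows — because the window is the classification atom and no
   overlap is assumed for training data.
6. **Artifact rejection.** Any window containing a sample with
   |amplitude| > 100 µV on any channel is dropped whole. The amplitude
   rule is interpreted as absolute (not peak-to-peak), and rejection is
   at window granularity rather than sample interpolation: windows are
   the atoms, and partial windows would break the per-second
   bookkeeping.

Readers exist for BrainVision (`.vhdr`/`.vmrk`/`.eeg`), EDF+ and a
JSON-plus-binary internal container; all three round-trip through their
paired writers (bit-exactly for the internal format, to float32 /
16-bit quantisation for the other two).

## Welch band-power features

For each window and channel, the power spectral density is the average
of modified periodograms: the signal is split into `L` segments of `M`
samples (step `M(1−overlap)`), each segment is tapered by `ω(n)` and
Fourier transformed, and

$$P(f) \;=\; \frac{1}{L}\sum_{i=1}^{L}
  \frac{1}{M\,U\,f_s}\Big|\sum_{n=0}^{M-1} x_i(n)\,\omega(n)\,
  e^{-j2\pi f n / M}\Big|^2 ,
\qquad U = \frac{1}{M}\sum_{n=0}^{M-1}\omega^2(n).$$

`U` makes the tapered periodogram asymptotically unbiased as a density;
for a rectangular window `U = 1`. The one-sided spectrum doubles all
bins except DC and Nyquist, and carries density scaling (power per Hz),
so summing `P(f)·Δf` recovers the signal variance (tested as a
Parseval property, within 10% on average over 100 white-noise draws —
a single Hanning periodogram is itself a high-variance estimate, which
is the point of Welch averaging).

For 1-s windows at 100 Hz the default configuration is
`M = nfft = 100`, no overlap, Hanning taper — the only setting that
produces 1-Hz bins over 0–50 Hz (51 bins) from a single window;
multi-segment configurations remain available for longer inputs. Values
are converted to dB (`10·log10`, floored at 1e−12 to avoid log of
zero) and z-scored **per channel within each window**. Normalising per
sample rather than over a training corpus keeps the transform
stateless, which the online path requires; the alternative
(corpus-level normalisation) would couple every prediction to training
statistics.

Band blocks are θ = 4–8 Hz (5 bins), α = 8–13 Hz (6 bins),
β = 13–35 Hz (23 bins), edges inclusive so adjacent bands share their
edge bin — the only reading that yields the 5/6/23 row counts the
models are built around. The classical-classifier feature vector
reduces each band to its mean per channel and concatenates θ‖α‖β:
59 × 3 = 177 features. The reducer is pluggable; the mean is the
conventional band-power summary.

## The gated recurrent unit

The GRU is implemented from first principles and is the package's
reference recurrent cell:

$$z_t = \sigma(W_z[h_{t-1}, x_t]), \quad
  r_t = \sigma(W_r[h_{t-1}, x_t]), \quad
  \tilde h_t = \tanh(W[r_t \odot h_{t-1}, x_t]),$$
$$h_t = (1 - z_t)\odot h_{t-1} + z_t \odot \tilde h_t .$$

No bias terms appear in these expressions, so none are used by default
(a flag adds them for parity with common variants). The concatenation
order is state-then-input, following the equations verbatim. `h₀ = 0`
unless supplied. Weights initialise uniform(−k, k) with
`k = 1/√hidden`, the standard recurrent scheme. A deliberately naive
scalar-loop evaluation (`gru_step_reference()`) serves as the
correctness oracle for the vectorised cell and the batched training
path; backpropagation-through-time gradients are verified against
finite differences in the test-suite. Because `h_t` is a convex
combination of `h_{t-1}` and a tanh output, `|h₀|∞ ≤ 1` implies
`|h_t|∞ ≤ 1` for all t, and a closed update gate (`z → 0`) preserves
the state exactly — both tested analytically.

## EEGNet and its band adaptation

EEGNet is the compact convolutional EEG architecture: a temporal
convolution (`F1 = 16` filters, kernel 50, same padding), batch norm, a
depthwise convolution spanning the full channel axis (C × 1, depth
multiplier `D = 2`), batch norm + ELU, average pooling (1,4), dropout,
a separable convolution (depthwise 1×16 then pointwise to
`F2 = D·F1 = 32`), batch norm + ELU, pooling (1,8), dropout, flatten,
dense softmax. `eegnet_shape_trace()` computes every layer's output
shape symbolically (flatten length `F2 · ⌊⌊T/4⌋/8⌋`, i.e. `F2·(T//32)`)
and the runtime tensors are tested against it layer by layer. The whole
network — forward, backward, Adam — is written in plain R with im2col
matrix products; every analytic gradient is checked against finite
differences.

Two modes exist. **Raw mode** takes 59 × 100 windows (the standalone
EEGNet baseline). **PSD mode** takes a band block whose frequency axis
plays the role of time — the only axis of length > 1 besides channels
in a 5/6/23 × 59 input. The raw-mode pooling (4, 8) would collapse a
5- or 6-bin axis below one position (`6//4//8 = 0`), so
`adapt_config_for_band()` shortens the temporal kernel to `min(50, T)`,
shrinks the separable kernel to the pooled length, and picks pooling
factors that leave a nontrivial sequence for the recurrent stage:
θ (2,1) → length 2, α (2,1) → 3, β (2,2) → 5.

Fixed training settings: Adam at learning rate 0.001, cross-entropy
loss, batch 64, dropout 0.25, 300 epochs at full scale. Batch-norm
momentum 0.99 and ε = 10⁻³ (unstated anywhere; conventional values). A
depthwise max-norm constraint appears in some EEGNet variants but not
in the parameterisation adopted here, so it is omitted by default.

## GRU-EEGNet: the composite model

Each band branch reads the pre-flatten feature map (`F2` features ×
`T′` pooled positions) as a `T′`-step sequence of `F2`-vectors feeding
a GRU (hidden size 32, matching `F2` and keeping the stage-2 parameter
count small). This within-sample sequence is the only sequence
available between the flatten and dense layers, which is where the
recurrent stage sits; an alternative reading (sequences of consecutive
windows) is representable by stacking windows but is not the default.
Each branch ends in its own dense softmax; the default fusion averages
the three branch distributions (equal-weight late fusion), with a
concatenated-GRU-state joint dense layer available as the alternative.
With averaged-softmax fusion there are no fusion weights, and stage 2
optimises the mean of the per-branch cross-entropies while the fused
accuracy is monitored.

Training is two-stage: stage 1 trains the three band EEGNets
independently (batch 64, 300 epochs, dropout 0.25); stage 2 freezes
every EEGNet weight — the trunks' parameters are fingerprinted before
and after and must be bit-identical — and trains the GRUs and heads
(batch 16, 100 epochs, dropout 0.5 on the GRU state). Stage-1
classification heads are discarded; only the convolutional trunks are
reused. Because the trunks are frozen, their feature sequences are
computed once and stage 2 runs on those, which is mathematically
identical and much faster. Task subsets (`fv` … `fvac`) are a label
filter, not an architecture change.

## Classical baselines

`train_psd_svm()` fits an RBF-kernel SVM (one-vs-one for multi-class)
on the 177-dim band features, enforcing the feature-width contract.
Hyperparameters are the library-conventional defaults (`C = 1`,
`γ = 1/(d·var)`); they are recorded with results. `compare_classifiers()`
runs decision tree, linear discriminant analysis ("discriminant
analysis" is read as LDA — nothing distinguishes quadratic variants),
naive Bayes, RBF SVM, kNN (k = 5), and a one-hidden-layer 64-unit
neural network over the seven task codes with stratified 5-fold CV.
All accuracies are out-of-fold.

`full_vs_band_features()` compares the 177-dim three-band features with
the full 0–50 Hz feature set (51 bins × 59 channels, same
dB-normalisation — chosen for symmetry with the model inputs) using the
same C-SVC in both arms on identical folds. Pairwise squared distances
are cached per arm so fold-seed sweeps are cheap; `γ` is recomputed on
each training fold.

## The synthetic generator

`simulate_design()` reproduces the experiment's structure: 7 laps of
~300 s, up to 12 distractor subtasks per lap placed uniformly at random
without overlap (exactly 84 distractor events at full density), types
uniform over visual/auditory/cognitive, 5-s focused trials carved out
of every sufficiently long inter-event gap, and an optional
invalid-trial probability for the missed-feedback mechanism.

`simulate_eeg()` builds each channel as: 1/f^a background noise
(spectral shaping, exponent 1 by default, 8 µV RMS), plus θ/α/β
oscillations synthesised as narrowband-filtered Gaussian noise — not
pure sinusoids, so spectral estimates carry realistic variance — whose
amplitudes are multiplied by the active state's gains during each
event, plus white sensor noise (1 µV). Gains encode the qualitative
physiology the decoder exploits: cognitive θ×2.0/α×1.6
(frontal/parietal), visual α×0.5/β×0.6 (parietal/occipital
suppression), auditory α×2.0 (temporal/central); focused is the unit
gain by definition. Channels outside a state's primary region receive a
log-damped version of the effect (exponent 0.4), giving topographic
structure without claiming fidelity to real scalp maps. The `strength`
parameter exponentiates all gains; strength 0 is the exact null.

Two state-independent nuisance components with segment-varying
(log-normal) amplitude are included: low-frequency drift (0.3–3 Hz,
base 6 µV) and EMG-band noise (38–48 Hz, base 3 µV). They emulate the
movement-related nonstationarity that real driving EEG suffers and
place non-discriminative variance outside the θ/α/β range — precisely
the condition under which restricting features to the informative bands
can pay off, and without which the full-band and band feature sets are
near-equivalent by construction (per-channel z-normalisation spreads
band-power shifts across all bins).

What passing tests on this generator do **not** show: realism of scalp
topographies (no forward head model), ocular artifacts beyond amplitude
spikes, inter-subject variability, or the actual effect sizes of human
distraction EEG, which the source experiments do not quantify. Results
on synthetic data demonstrate that the pipeline recovers planted
structure of plausible form, not field performance.

## Evaluation and the online loop

`compute_metrics()` derives accuracy (%), Cohen's κ (chance agreement
from the confusion-matrix marginals — the multi-class definition),
macro (unweighted) F1, and per-class precision/recall from one
confusion matrix; the hand-checked arithmetic is frozen in the tests.
`kfold_cv()` uses class-stratified folds; every sample is tested
exactly once. `replay_online()` pushes a labelled recording through the
online preset (0.1–45 Hz, 100 Hz), slices each event into 1-s chunks
aligned to event boundaries — the per-second counting implies aligned
chunks (a 15-s auditory event contributes exactly 15 tallied windows) —
predicts each, and produces the per-state presented/correct tally whose
overall accuracy is ΣC/ΣT. The published per-subject tally counts and
per-subject metric table ship as reference CSVs, and the package
re-derives their printed summary statistics from the raw counts.

## Problem sizes, seeds and numerics

The shipped test-suite and acceptance script run entirely on generated
data, sized for a single CPU: fixtures are simulated at 200 Hz over
64 channels (the generator's defaults remain 1000 Hz; band content
lives below 35 Hz so the scale choice does not touch the science), the
four-class training fixtures hold ~800 windows, and the two-stage
schedule for these runs is 30 stage-1 / 20 stage-2 epochs — enough for
the strong-effect fixture to exceed 80% held-out accuracy by a wide
margin. Every random draw flows from an explicit seed: generation,
fold assignment, weight initialisation, shuffling and dropout are all
reproducible, and identical seeds give bit-identical models.

Numerical choices: dB floor 1e−12; softmax computed with max
subtraction; a zero-variance channel after the dB transform is
zero-filled and flagged rather than producing NaNs; prediction ties
break by the fixed class order (focused, visual, auditory, cognitive);
pooling truncates trailing positions (floor semantics) exactly as the
shape calculus specifies; cross-entropy is floored at 1e−12 and a
non-finite loss aborts training with the epoch index.

## Known limitations

* The networks are plain-R implementations tuned for the package's
  problem sizes; they are not a GPU framework, and raw-mode EEGNet at
  full scale (59 × 100 × thousands of windows × 300 epochs) is
  compute-hungry.
* Live acquisition (TCP streaming) is out of scope; the online loop is
  a file-replay simulation with the same preprocessing.
* The EDF writer emits one-second records and requires whole-second
  recordings; BrainVision support covers the float32 multiplexed
  dialect (plus int16 reading).
* No 10-channel reduced montage is defined anywhere in the source
  material, so only the 59-channel analysis montage is implemented.
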