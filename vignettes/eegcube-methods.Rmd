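---
title: "Methods: 3D spatiotemporal EEG representations and channel-bottleneck 3D CNNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D spatiotemporal EEG representations and channel-bottleneck 3D CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, how they were resolved, and what the shipped
tests do and do not establish.

## 1. From raw trials to 3D tensors

A trial is a channel-major matrix of EEG amplitudes (µV) with a sampling
rate and two 1–9 self-assessment ratings (valence, arousal). The pipeline
is: trim the pre-stimulus prefix (default 3 s of a 63-s trial, leaving
60 s); cut into non-overlapping windows (default 1 s; trailing samples that
do not fill a window are discarded — the floor rule follows from fixed
tensor depth plus non-overlap); and render every window as a
depth × side × side tensor, one spatial map per time sample.

Per time sample:

1. **Grid projection.** The 32 channel values are placed on a 9×9 grid by a
   fixed electrode-to-cell table (rows anterior→posterior, columns
   left→right, midline in column 4, 0-based). The published layout figure
   for this montage is not machine-readable, so the shipped table
   (`inst/extdata/deap_montage_9x9.json`) is a documented,
   topology-preserving convention, versioned and overridable by any JSON
   file with the same schema — not a verified transcription.
2. **Thin-plate-spline fill.** The 49 electrode-free cells are interpolated
   from the 32 occupied cells with the thin-plate kernel r² log r plus an
   affine polynomial term, nodes and evaluation points at cell centers. The
   generic "RBF interpolation" admits many kernels; the thin-plate choice
   was made because it is parameter-free (no shape parameter to tune) and
   reproduces constant and planar fields exactly, which gives sharp,
   testable invariants. It interpolates: occupied cells are never altered.
   All 49 empty cells of the full square are filled — no scalp mask —
   because the downstream network consumes a dense grid. Fewer than three
   or collinear nodes make the affine part unidentifiable and raise an
   error.
3. **Bicubic upsampling.** The 9×9 map is resampled to 64×64 (side
   configurable, upsampling only) with the Keys cubic kernel, a = −0.5,
   separable in rows and columns. "Bicubic" is a family, not a single
   algorithm, so the dialect is pinned explicitly: align-corners coordinate
   mapping (source corners map exactly to target corners) and mirror
   (reflect-without-repeat) border handling. Kernel weights at any target
   coordinate sum to 1, so constants survive exactly; the unit tests also
   compare against an independent, non-separable direct evaluation of the
   same kernel.

The default pipeline applies no amplitude normalization (an optional
per-channel z-scoring flag exists on `build_dataset()`); consequently the
whole representation is linear in the input amplitudes, and scaling a trial
by *s* scales every tensor entry by *s* — a tested property. With fixed
inputs the pipeline is bit-deterministic.

Both interpolation stages are linear maps with geometry fixed by the
montage, so `build_window_tensor()` precomputes the 49×32 fill operator and
the two 64×9 bicubic weight matrices once per window; a full 128×64×64
window renders in tens of milliseconds.

## 2. Architectures as declarative specifications

`model_spec` is an ordered list of layer records (conv3d, batchnorm, relu,
maxpool3d, flatten, dense, dropout, lstm, tanh, last-step). Shape tables
(`forward_shapes`), layer censuses (`layer_census`), parameter and FLOP
accounting (`count_parameters`, `count_flops`) and the numeric engine
(`instantiate_model`, `nn_forward`, `train_model`) all consume the same
record, which is what makes the architecture claims auditable.

**CNN-BN** (`build_cnn_bn`): stem 7×3×3 conv (1→64) + BN + ReLU + 2×1×1
pool; five bottleneck blocks (C_bn, C_out) = (16,128), (32,256), (64,256),
(64,256), (64,256), each 1×1×1 reduce → 7×3×3 at the reduced width → 1×1×1
expand, BN + ReLU after every conv, then 2×2×2 pool; flatten (2048) →
dense(C_mid) → ReLU → dropout 0.5 → dense(2). The published table never
prints a padding; 7×3×3 convolutions preserving D, H, W at stride 1 force
padding 3×1×1, which the builder states explicitly. Max pooling demands
exact divisibility and names the offending stage otherwise — silent floor
semantics would break the declared shape table.

Two open points are resolved as follows. *Conv biases:* unstated in the
source material; included by default (conservative for parameter counts),
removable via `conv_bias = FALSE` since batch norm makes them redundant.
*Dense width:* the architecture table prints C_mid = 128, but the published
1.11 M parameter total is consistent with C_mid = 64 (1,108,834 vs
1,240,098 at 128). Both are supported: the complexity-report profile uses
64, the training default 128.

**C3D baseline** (`build_c3d`): six blocks of 7×3×3 conv + BN + ReLU +
pooling (2×1×1 after block 1, 2×2×2 after blocks 2–6), dense 512 → 2. The
baseline's internal widths are not published; the default schedule (64,
128, 256, 256, 256, 256) was chosen as the plausible full-width schedule
whose closed-form totals agree with the published figures (parameters
within 0.2 %, FLOPs within 0.15 %), and every element is overridable.

**LSTM baseline** (`build_lstm`): three stacked LSTM layers (hidden width
128 — unpublished, a convention here) each followed by tanh, on raw 1-s
windows as 128 time steps × 32 features; the last time-step state feeds
dense(128) → ReLU → dropout 0.5 → dense(2).

## 3. Complexity accounting

Parameters: conv C_out·C_in·d·k² (+C_out bias); batch norm 2C; dense
out·in + out; LSTM layer 4(h(in+h) + 2h) (four gates, both bias sets).
FLOPs: 2 per multiply-accumulate for conv/dense/recurrent layers, plus
selectable elementwise add-ons — batch norm 2 ops/element, ReLU/tanh 1,
max pooling (kernel volume − 1) comparisons per output element; bias
additions excluded by default. There is no universal FLOP convention;
2×MACs-plus-add-ons is used because it is the most common reporting
convention and reproduces the published baseline total to well under 1 %.
The remaining few-percent gap on the bottleneck model's total is convention
ambiguity (treatment of bias/BN/pooling by the original counting tool is
unknown), and the acceptance tests therefore assert a declared 5 % band for
that one quantity, 1 % elsewhere.

Reduction percentages are computed from the two-decimal rounded
millions/giga values — matching how such tables are printed — as
100 (1 − small/large), rounded half-up to 2 dp. `count_parameters()` is
cross-checked in the tests against direct enumeration of instantiated
parameter arrays, exactly, for all model families.

`measure_inference_time()` reports median wall-clock per forward pass; it
is hardware- and backend-dependent and deliberately outside every
validated claim.

## 4. Training and evaluation

Softmax cross-entropy over two logits (natural log; probability-form
`cross_entropy_loss()` clips at 1e−7), plain SGD (momentum and weight decay
default 0, configurable), mini-batch 32, initial learning rate 0.01 decayed
×0.9 every 10 epochs — `lr(e) = 0.01·0.9^⌊(e−1)/10⌋` — for a fixed 90-epoch
budget (no early stopping). Ratings binarize at 5 with the boundary
assigned to *low*; conventions differ in the literature, so the rule is
explicit and tested. Splits are uniform window-level 80/20, repeated five
times with seeds `seed + r`; metrics aggregate as mean and *population* SD
(n = 5 repeats is a complete set, not a sample). Window-level splitting
mirrors the reference protocol but lets windows of one trial land on both
sides of the split, leaking trial identity; a user who wants leakage-free
estimates should split at trial level before building windows — the
provenance table makes that possible.

The engine computes exact gradients (verified against central finite
differences through a conv + BN + ReLU + pool + dense stack), uses batch
statistics in training and running averages (momentum 0.1) in evaluation,
inverted dropout, and Kaiming fan-in initialization (orthogonal per-gate
recurrent matrices for LSTM). Determinism: initialization, shuffling and
dropout all draw from the single seeded RNG stream, so identical seeds give
bit-identical runs. Training a NaN loss aborts with a diagnostic.
Backpropagation covers the feed-forward layer kinds; the LSTM baseline
supports construction, complexity accounting and numeric forward passes,
but not training — within this package it serves as an architecture and
complexity reference, and `train_model()` says so in its error message.

## 5. The synthetic generator

Each channel is 1/f-shaped Gaussian background noise (default exponent 1,
sd 10 µV) plus one sinusoid per band — theta 4–7 Hz (4 µV), alpha 8–13 Hz
(10 µV), beta 14–30 Hz (5 µV) — with uniformly drawn frequency and phase.
Class effects: high valence multiplies left-frontal (Fp1, AF3, F3, F7, FC5)
alpha amplitude by 1 + δ and right-frontal (Fp2, AF4, F4, F8, FC6) by
max(0, 1 − δ/2) — a frontal-alpha-asymmetry mechanism; high arousal
multiplies beta amplitude on frontal-central channels (Fz, Cz, FC1, FC2,
FC5, FC6) by 1 + δ. These mechanisms are literature-motivated conventions
chosen so that both the spatial and the temporal pathway of the network
carry class signal; they claim nothing about the true generative process of
real recordings. δ = 0 yields class-indistinguishable data. Trials are
assigned to the four valence × arousal classes round-robin (10 each per
40-trial subject), ratings are drawn uniformly from (5, 9] / [1, 5]
consistently with the class, and the archive mirrors the per-subject array
layout (data: trials × 32 × 8064; labels: trials × 4, dominance/liking as
uniform filler).

`band_power_probe()` verifies the effect-size dial: Welch band powers (1-s
Hann segments, 50 % overlap) averaged within the three channel groups, six
log-power features, a logistic probe on a random half of the trials, and
the rank (Mann–Whitney) AUC of its held-out scores. The tests pin chance
behaviour at δ = 0 and monotone growth of the AUC over
δ ∈ {0, 0.5, 1, 2, 5}.

What the generator does *not* emulate: ocular/muscle artifacts, volume
conduction, inter-subject variability, non-stationarity, or any real
coupling between affect and EEG. Green pipeline tests on synthetic data
therefore establish that the machinery is correct and sensitive to planted
band-power structure — not that the classifier reaches any particular
accuracy on real recordings. Reproducing the published headline accuracies
would require the access-gated recordings and GPU-scale training and is
intentionally out of scope.

## 6. Desk-scale study sizes

The shipped tests exercise the full-resolution representation (60 windows
of 128×64×64 from a 63-s trial; single windows end-to-end) but train only
width-reduced networks on reduced windows — 0.25-s windows rendered at
16×16 (the smallest side not below the 9×9 source), a stem of 4 channels
and two bottleneck blocks (2→8, 4→16) with a 32-wide dense head (~35 k
parameters). These sizes are the package's chosen desk-scale study
conditions: large enough that the network must actually learn the planted
spatial/temporal structure (64 windows, δ = 5, ≥ 95 % training accuracy
within 200 epochs; in practice it converges within ~10), small enough to
run routinely. The chance-level check trains the same reduced family on 192
δ = 0 windows over five seeded repeats and expects mean held-out accuracy
in [0.40, 0.60]. For these short runs the smoke configuration uses learning
rate 0.02 with momentum 0.9 and batch 16 — a standard small-batch setting;
the protocol defaults (0.01, momentum 0, batch 32, 90 epochs) remain the
package defaults.

## 7. Storage formats

Archives and window datasets are stored as R-native RDS files, and model
specs / complexity reports / the montage as JSON. The spec's HDF5/NPZ
archive suggestion presumes a Python stack; RDS is this package's native
equivalent (exact round trips, one-call IO) and the round-trip property is
tested. A converter path for the original pickled per-subject files is
documented in `?load_deap_preprocessed`, which validates array shapes and
rating ranges and discards the eight peripheral channels.

## 8. Known limitations

- The electrode-to-cell table is a convention; a different plausible layout
  changes the spatial maps (not the shape/complexity claims).
- The bottleneck FLOP total is convention-dependent at the few-percent
  level; the declared band makes that explicit.
- No LSTM training; no GPU; single-threaded compiled kernels — adequate for
  desk-scale training, not for full-resolution 90-epoch runs.
- Window-level splits leak trial identity (see §4); headline accuracies
  obtained under such splits overstate generalization to unseen trials.
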