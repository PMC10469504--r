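---
title: "Decoding motor imagery with sliding-window tokenization and two-stage attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery with sliding-window tokenization and two-stage attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnmi)
```

## The decoding problem

Motor-imagery (MI) EEG decoding asks which movement a subject is imagining
— left hand, right hand, foot or tongue in the four-class benchmarks —
from a short multichannel EEG trial.  The exploitable physiology is
event-related desynchronisation (ERD): imagining a movement attenuates
mu/beta-band oscillatory power over the corresponding patch of motor
cortex.  A trial is a `C x T` matrix (electrodes by samples, microvolts);
the classifier must find spatially localised, band-limited, temporally
extended power changes in it.

## The model

`attnmi` implements a compact convolution-plus-attention classifier in
three blocks.

**Convolutional block.**  Three convolutions with two poolings:

1. *Temporal* convolution: `F1` kernels of length `Fs %/% 4` (a quarter
   second), shared across electrodes, "same"-padded, followed by batch
   normalisation.  Each kernel is a learned temporal filter, so this stage
   plays the role of a data-driven filter bank.
2. *Depthwise channel* convolution: for each of the `F1` maps, `B` kernels
   spanning all `C` electrodes collapse the spatial axis, yielding
   `F2 = F1 * B` feature maps — learned spatial filters in the EEGNet
   tradition.  Batch normalisation, ELU, average pooling by `P1`, dropout.
3. *Local temporal* convolution: one length-16 kernel per map, "same"
   padded; batch normalisation, ELU, average pooling by `P2`, dropout.

The result is a sequence of `Tz = (T %/% P1) %/% P2` tokens, each an
`F2`-vector (the published configurations give `Tz = 20` for 22-channel,
1125-sample trials at 250 Hz and `Tz = 11` for 18-channel, 640-sample
trials at 160 Hz).  `Tz >= 4` is required; shorter trials are rejected at
configuration time.

**Sliding-window block.**  The token sequence is re-organised into
`L = Tz %/% 4 + 2` overlapping views:

- `Tz %/% 4` *continuous* windows: stride-2 blocks of `Tz %/% 2`
  consecutive tokens (window `i` covers positions
  `2i - 1 .. 2i + Tz %/% 2 - 2`);
- 2 *dilated* windows: the odd-position and the even-position tokens,
  truncated to the first `Tz %/% 2` members so all windows share one
  length (for odd `Tz` the final token goes unused — the price of a
  rectangular window tensor).

A trainable *type token* (one vector for continuous, one for dilated
windows, shared across all windows of its kind) is prepended to every
window, marking its construction kind for the attention stages.

**Attention block.**  Multi-head self-attention (MSA) with a two-stage
pre-norm residual design: each window is processed independently by a
*local* site (`z + MSA(LN(z))`, one parameter set shared across windows),
the windows are concatenated into one sequence of
`L * (Tz %/% 2 + 1)` tokens, and a *global* site applies the same form
over the whole sequence.  The MSA uses a double projection: the sequence
is first mapped to `q, k, v` by `F2 x F2` matrices, then each of
`h = F2 / Dh` heads applies its own `F2 x Dh` map; scaled dot-product
attention (`softmax(q k' / sqrt(Dh)) v`) runs per head, the head outputs
are concatenated and mapped back to `F2` by a trainable output
projection.  The classifier head applies layer normalisation, a
token-wise two-layer MLP (hidden width `F2`, ELU) with a residual
connection to its input, flattens the sequence, and ends in a dense
softmax layer over the classes.

Four ablation switches bypass individual pieces: without the sliding
window the token sequence feeds the global stage directly; without the
type token windows carry no marker slot; without local attention windows
pass to concatenation unchanged; without global attention the sequence
goes straight to the head.  Only 10 of the 16 combinations are legal (the
type token and local attention presuppose windows); `ablation_variants()`
enumerates exactly those ten.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `F1` | 16 | temporal filters |
| `B` | 2 | depthwise kernels per filter (`F2 = 32`) |
| `P1`, `P2` | 8, 7 | pooling widths (set `Tz`) |
| `Dh` | 8 | head size (`h = F2 / Dh = 4` heads) |
| dropout | 0.3 / 0.3 / 0.5 | conv block / windowed tokens / attention weights |
| optimiser | Adam, lr 0.009, batch 64 | cross-entropy loss |

These are the published settings and the package defaults; everything is
adjustable through `model_config()` and `train_config()`.

## Numerical choices

All forward and backward passes are hand-written matrix code (plus three
small C++ kernels for the batch-normalisation passes and the temporal
convolution's column expansion, which dominate profiles).  Choices a
reimplementer must make somewhere:

- *Integer divisions*: `Tz` uses sequential floor division
  `(T %/% P1) %/% P2`, matching two pooling layers applied in turn; all
  window counts and lengths floor.
- *Attention scale*: `1 / sqrt(Dh)`, the standard scaled dot product.
- *Head combination*: concatenation of per-head outputs followed by a
  trainable output projection (the standard transformer form).
- *Residual parenthesisation*: both attention sites are pre-norm,
  `z + MSA(LN(z))`.
- *Classifier input*: the full post-attention sequence is flattened; the
  type tokens are not used as designated readouts.
- *Batch norm*: momentum 0.99, variance floor 1e-3 (TensorFlow/Keras
  defaults, matching the provenance of the architecture); layer-norm
  epsilon 1e-5.  Inference uses running statistics, so repeated forward
  passes are bitwise identical.
- *Initialisation*: Glorot-uniform for all dense/convolutional maps,
  N(0, 0.02) for type tokens; one seed threads through initialisation,
  shuffling and every dropout draw, so training runs are exactly
  reproducible.
- *Ties*: argmax prediction breaks ties toward the lowest class index.
- *Kappa*: Cohen's kappa from the confusion-matrix marginals,
  `(Po - Pe) / (1 - Pe)`.  A per-class-averaged variant (mean of
  one-vs-rest binary kappas) is available via
  `cohen_kappa(variant = "per_class")` for comparison with reports that
  sum kappa over classes with a `1/Nc` factor; the marginal form is the
  default because it reproduces the accuracy-kappa pairings quoted for
  four-class BCI benchmarks (e.g. accuracy 0.861 pairing with kappa near
  0.81 under near-balanced marginals).

## The synthetic generator

No public MI-EEG data ships with the package; `generate_epochs()` makes
labelled trials whose class structure mimics ERD:

- every channel carries a band-limited oscillation (random frequency in
  `osc_band`, default the 8-12 Hz mu band; random phase per channel;
  amplitude 1) plus white Gaussian noise (`noise_sd`, default 0.5);
- during the middle half of the trial, with 10%-of-`T` linear onset and
  offset ramps, the oscillation on the label's channel group is
  multiplied by `1 - erd_depth` (default 0.9).

The default study conditions are 4 classes x 100 trials, 16 channels in
four disjoint 4-channel groups, 2-s trials at 128 Hz.  They pair with
`model_config(16, 256, 128)` — the full architecture at its published
hyperparameters with `Tz = 4`, the smallest legal token count — so that
complete training runs finish in minutes on one core.  The vignette-scale
sanity runs use 64 trials (200 epochs) for memorisation capacity and 400
trials with a 90/10 stratified split (80 epochs) for generalisation;
those sizes are the package's desk-scale convention, also used by the
test suite.

What the generator does *not* emulate: 1/f background spectra (optional,
off by default to keep the band-power oracle simple), volume conduction
and channel correlation, artefacts, non-stationarity, inter-subject
variability (subjects are i.i.d. blocks with identical statistics).
Passing the learning-sanity tests therefore shows the pipeline can
discover genuine spatial band-power structure end to end — it does not
certify benchmark-level accuracy on real recordings, which the package
makes no claim about.

A deliberately simple oracle, `bandpower_baseline()` (per-channel log
band power over the middle half, nearest class centroid), verifies
independently of the network that generated data carry the intended
class signal: at the default conditions it classifies held-out trials
near-perfectly, and at `erd_depth = 0` it sits at chance.

## Cross-validation protocols

`make_splits()` builds the two protocols used by the four-class
benchmarks: stratified within-subject k-fold (class-stratified with
seeded shuffling, fold sizes differing by at most one — 84 trials under
10-fold give test folds of 8 or 9) and between-subject leave-groups-out
(whole subjects per fold: 9 subjects under 9-fold is
leave-one-subject-out; 109 subjects under 11-fold give test folds of 9
or 10 subjects).

## Design decisions taken here

Where the architecture description leaves room, the package fixes:

- dilated windows for odd `Tz` are truncated (not ragged ceil/floor) so
  the window tensor stays rectangular;
- one local-attention parameter set is shared across windows, keeping the
  parameter count independent of `L`;
- the concatenated sequence keeps the type-token slots;
- the MLP hidden width equals `F2` so the head's residual is well-typed;
- ablation variant 1 keeps the full head (LN + residual MLP + dense),
  so variants differ only in the bypassed blocks;
- no learning-rate schedule, weight decay, early stopping, augmentation
  or max-norm constraints.

## Limitations

- Real GDF 2.x recordings are not parsed; EDF/EDF+ is the supported real
  interchange format, and GDF support covers only this package's own
  GDF1-style fixtures.
- Training is CPU matrix code: ~1 s per 64-trial batch at the desk-scale
  configuration. Full-scale benchmark replication (1000 epochs, 288-trial
  sessions at `C = 22`, `T = 1125`) is supported by the same code paths
  but takes hours, and the published accuracies additionally require the
  original datasets, which must be obtained separately.
- The chance-level and monotonicity checks are statistical; they use
  3-standard-error bands and can in principle flake under adversarial
  seeds, though the shipped seeds are fixed.
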