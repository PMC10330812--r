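---
title: "Temporal contrastive pretraining for task fMRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal contrastive pretraining for task fMRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Decoding the cognitive task a person performed from 4-D task fMRI works
well with deep networks, but labelled fMRI is expensive: typical studies
have a few dozen subjects, far below what end-to-end 3-D networks need.
`fmricontrast` implements a self-supervised route around this: pretrain a
volumetric encoder on *unlabelled* fMRI using only the passage of time as
supervision, then fine-tune the pretrained weights on the small labelled
problem of interest.

The pretext task exploits a basic property of BOLD signals: temporal
autocorrelation. Activity patterns close in time are more alike than
patterns far apart in time. Each training clip (one task block plus
padding) is divided into a beginning, a middle and an end segment of `k`
frames each. The encoder maps each segment to a vector in *contrast space*,
and the loss demands that the middle and end segments (temporally adjacent)
be more similar there than the beginning and end segments (temporally
distant):

$$\mathcal{L} = -\log\frac{e^{\mathrm{sim}(y_2, y_3)}}
{e^{\mathrm{sim}(y_2, y_3)} + e^{\mathrm{sim}(y_1, y_3)}},
\qquad \mathrm{sim}(x, y) = \frac{x \cdot y}{\lVert x\rVert_2\,\lVert y\rVert_2},$$

where $y_1, y_2, y_3$ embed the beginning, middle and end. This is a
two-term softmax cross-entropy in the similarities; both similarities lie
in $[-1, 1]$, so the loss is confined to
$[\log(1+e^{-2}), \log(1+e^{2})] \approx [0.127, 2.127]$, with
$\log 2 \approx 0.693$ the indifference point. Some write-ups print this
loss with $\mathrm{sim}(y_1, y_3)$ in the numerator while defining
middle–end as the positive pair in the text; `triplet_loss()` implements
the positive-pair-in-the-numerator semantics (that is what gradient descent
must maximise) and exposes `pair_order = "printed"` to run the literal
index order for comparison.

No temperature parameter is used: the loss as stated has none, and we did
not add one.

## Triplet geometry

For a clip of `T` frames and segment length `k` (disjoint mode), the clip
is partitioned into three contiguous thirds and one `k`-frame window is
placed inside each third — at a uniformly random valid offset during
training (a mild temporal augmentation) and centered during evaluation.
`T >= 3k` is required. The construction guarantees order (beginning <
middle < end by start frame) and pairwise disjointness.

The overlapped variant (an ablation) demands that the middle segment
overlap each neighbour by exactly `o` frames while beginning and end stay
disjoint. Exact overlap is rigid: it forces the chain `begin = a`,
`middle = a + k - o`, `end = a + 2(k - o)`, leaving only the global offset
`a` free (centered or random). At `T = 21, k = 9, o = 3` the chain
`[0,9), [6,15), [12,21)` is the unique admissible placement, which the test
suite verifies by enumeration. `2o <= k` is enforced so beginning and end
cannot touch.

Before segmentation each clip is normalised. The default
(`normalize = "voxel"`, `normalize_voxelwise()`) subtracts every voxel's
temporal mean and rescales the demeaned clip by one global standard
deviation. The reasoning is quantitative: raw fMRI intensities carry a
static anatomical structure (baseline inside the brain vs ~0 outside)
that is orders of magnitude larger than any task response. A plain global
z-score (`normalize_clip()`, also provided) keeps that structure and its
huge variance in the divisor, leaving the response at a few percent of a
standard deviation — we measured that *no* amplitude of simulated task
signal survives it at desk scale. Demeaning per voxel removes the static
anatomy exactly; scaling globally (rather than per voxel) preserves the
*relative* response amplitude across voxels, so how strongly and how
extensively a region responds remains visible — per-voxel z-scoring
(`"voxel_z"`, available) flattens every voxel to unit variance and erases
exactly that information. An all-constant clip maps to zeros. Raw values
are preserved through I/O — normalisation lives here, not in the reader.

## The encoder

The architecture follows the residual-network template, adapted to 4-D
input:

1. **Temporal stem** — a convolution whose kernel spans all `k` input
   frames at each 3×3×3 spatial neighbourhood, collapsing time into
   `base_channels` 3-D feature maps. Treating frames as input channels
   makes this a standard 3-D convolution. The stem uses spatial stride 2
   by default (`stem_stride`), mirroring the strided stem of residual
   image networks.
2. **Four residual stages** of two blocks each. A block is
   conv(3×3×3) → norm → ReLU → conv(3×3×3) → norm, added to an identity
   shortcut and rectified. Stages 2–4 enter with stride-2 downsampling and
   a projected (1×1×1, normalised) shortcut, doubling-ish widths
   (`stage_channels`, default 16-32-64-128).
3. **Global average pooling** over space, followed by a parameter-free
   layer normalisation of the pooled vector (below).
4. **Projection head** (pretraining): linear → ReLU → linear to
   `contrast_dim`. **Classifier head** (fine-tuning): the projection head
   is discarded and a single fully connected layer maps the
   `feature_dim`-vector to class logits.

Channel widths, kernel sizes, the normalisation and the pooling are our
choices — the architecture this follows is published only as a block
diagram, fixing the component sequence but none of the sizes — and all
are exposed in `encoder_spec()`. Defaults are sized to train on a CPU
over simulated volumes.

**Why instance normalisation.** Each conv is followed by instance norm
(per-sample, per-channel standardisation over voxels with a learned
affine) rather than batch norm. Instance norm keeps the forward pass of a
sample independent of its batch, which makes batched training an exact
gradient average over single-sample passes, keeps evaluation identical to
training mode, and needs no running statistics in checkpoints. At the last
stage the spatial extent can be a single voxel, where standardisation
would annihilate the signal (the mean equals the value); the layer then
degrades to its affine part.

**Why layer-normalise the pooled feature.** Average pooling of rectified
maps yields vectors dominated by a large input-independent component: at
initialisation, embeddings of *different* inputs have cosine similarity
≈ 0.99, leaving almost no contrast range and vanishing cosine gradients.
Z-scoring the pooled vector per sample removes that shared component
without introducing any cross-sample coupling. It sits between the
pooling and the head and has no learnable parameters.

**The engine.** No deep-learning framework is available to R here, so the
package carries its own: 3-D convolution as im2col + BLAS GEMM in C++
(RcppArmadillo), with hand-derived backward passes for every layer, Adam,
and an exhaustive finite-difference gradient test in the suite
(`test-encoder.R`). The backward pass of the stem skips the input-gradient
computation (nothing sits below it), and convolution biases that feed a
normalisation have an exactly zero gradient — both are checked, not
assumed.

## Optimisation

Pretraining uses Adam (β₁ = 0.9, β₂ = 0.999), batch 16, learning rate
1e-4 decayed by 0.99 per epoch, 100 epochs — the published recipe — as
`train_spec()` defaults. One triplet is drawn per clip per epoch with
fresh random placement; every clip is visited once per epoch in a seeded
shuffle; the final partial batch is kept. The entire run (initialisation,
shuffles, placements) is a pure function of two seeds (encoder, trainer),
and two runs with the same seeds produce bitwise-identical loss curves.

Fine-tuning (`finetune()`) attaches the linear classifier and minimises
cross-entropy end-to-end on randomly placed `k`-frame windows
(`sample_window()`); each clip is normalised (same modes as pretraining,
voxelwise demeaning by default) before the window is cut, so the
window's temporal statistics come from the whole clip.
Validation accuracy on centered windows drives a plateau schedule: when
the best validation accuracy has not improved for `plateau_patience`
epochs (strict comparison, tolerance 0), the learning rate is divided by
`plateau_factor` (default 10). We return the weights of the best
validation epoch rather than the last — with 30–60-epoch budgets on small
datasets the last epoch routinely overfits. The validation split holds
out one subject, or 10% of training subjects, whichever is larger;
validation subjects never appear in training.

## The simulator

`sim_spec()`/`generate_run()` emulate the statistical structure the
method relies on, not the anatomy:

* **Design**: `blocks_per_run` cycles of one task block
  (`block_duration_s`, default 16 s) centred in its block+rest cycle
  (`rest_duration_s`, default 10 s), so clip padding up to half the rest
  never leaves the run. The event table lists the blocks.
* **Signal**: boxcar ⊛ double-gamma HRF (gamma shapes 6 and 16, unit
  rate, undershoot ratio 1/6; peak ≈ 5 s, undershoot ≈ 15 s), peak
  normalised, times a task-specific spatial pattern times a per-subject
  gain (1 ± `subject_gain_sd`). Patterns are smoothed, thresholded
  Gaussian random fields shared across subjects. Tasks differ in three
  attributes: location (where the field lands), granularity (a fixed
  task-specific texture scale, 0.55–1.45 × `pattern_smoothness`) and
  extent (a task-specific threshold between 0.6 and 1.4 field sds, broad
  weak vs focal strong topographies), with a saturating soft edge so that
  total activation mass scales with extent. Location alone would make
  tasks provably indistinguishable to a translation-invariant
  convolution + global-pooling decoder — two equal-statistics random
  fields differ only in *where* — whereas real task contrasts also differ
  in extent and granularity across cognitive domains, which is what the
  extra attributes emulate.
* **Noise**: per-voxel AR(1) (`ar_rho`, default 0.4) with stationary
  start, optionally smoothed spatially (`noise_smooth_sd`); mixing
  equal-ρ AR(1) series leaves the lag-1 coefficient intact, and the noise
  is rescaled to `noise_sd` afterwards. Low-frequency drift is a random
  per-voxel polynomial (`drift_order`, default 2) on an orthogonal basis.
  `amplitude` scales the task signal relative to the noise sd.
* **Scaling**: baseline 100 inside an ellipsoidal brain mask —
  conventional fMRI units; removed by the default normalisation but it
  exercises the normalisation path.

Each run is a pure function of `(spec, subject, task)`; per-subject and
per-task seeds are derived from the master seed, so datasets are exactly
reproducible and any clip can be regenerated in isolation.

What the simulator does **not** model: head motion, physiological noise,
multiband artifacts, anatomical structure, spatial nonstationarity, or
between-task timing differences. Tests passing on this generator show the
machinery is correct and that the method behaves as claimed *under the
model's assumptions*; they do not certify performance on real scanners.

**Measuring the premise.** The claim "temporally close segments are more
alike" is quantified by `premise_correlations()`: each segment is averaged
over its `k` frames and the two mean volumes are correlated across voxels.
The per-voxel-per-frame alternative is hopeless at desk scale — for AR(1)
noise its expected middle–end minus beginning–end difference is of order
ρ^k (≈ 1e-4 at ρ = 0.4, k = 7), far below estimator noise — whereas means
of adjacent k-frame windows of an AR(1) process retain correlation ≈ 0.08
under the same conditions, yielding a measurable, sign-stable gap. On
raw (unnormalised) segments the absolute correlations sit near 1 because
all segments share the same anatomy; after the default voxelwise
demeaning they reflect the noise and response structure alone. Either
way the informative quantity is the difference, middle–end minus
beginning–end.

## Desk-scale study conditions

The training-based checks run at a deliberately small scale chosen once:
encoder with `base_channels = 4`, stages 4-8-16-16, `contrast_dim = 8`,
`k = 7`, on 16³ volumes.

**Pretraining corpus.** 200 clips from 20 subjects × 5 tasks × 2 blocks
per task at the simulator defaults — many subjects with few blocks each,
the composition of large public task-fMRI corpora. The composition
matters: with the same 200 clips drawn from only 5 subjects the encoder
memorises subject idiosyncrasies and the held-out separation vanishes.
Held-out evaluation uses 8 further subjects, centered segment placement.

**Optimisation at desk scale.** The published recipe (lr 1e-4, batch 16,
100 epochs) belongs to a ~65k-step regime; a desk-scale epoch has only
~13 such steps, where that recipe either under-trains or — at higher
rates — collapses to the constant-embedding solution (every segment
mapped to the same vector; the loss sits exactly at log 2). The
pretraining checks therefore run Adam at lr 3e-5 with batch 2 for 30
epochs (~3000 updates), keeping the published decay shape (0.99/epoch);
`train_spec()` defaults remain the published values. The checks assert
the *sign* of the held-out separation (in ≥4 of 5 seeds) and of the
transfer ordering, never magnitudes.

**Transfer protocol.** Two simulated tasks never seen in pretraining
(with large amplitude and a 36 s block/rest cycle so they are genuinely
decodable), a fixed held-out evaluation panel of 8 subjects, and per seed
a fresh draw of 6 fine-tuning + 2 validation subjects. Each arm
(pretrained vs random initialisation) is the mean test accuracy of two
weight/training draws — averaging over the initialisation lottery — and
the ordering is judged by a one-sided sign test across 12 seeds. The
fixed panel keeps the per-seed comparisons paired on the same evaluation
data.

## Numerical conventions

* Frames and voxels are indexed 0-based with half-open intervals
  everywhere (`[lo, hi)`); `bbox`, `source_span` and triplet spans all
  follow it. This keeps every worked arithmetic example exact.
* Seconds → frames via `round(duration / TR)`, halves away from zero;
  all published (frames, seconds) pairs for TR 0.72 s and 2 s reproduce
  exactly under this rule.
* Clip extraction is strict by default — a padded window leaving the run
  is an error, because silent truncation corrupts fixed-length batching;
  `mode = "clamp"` opts into truncation and records the actual span.
* Cosine similarity is clipped to [-1, 1] against roundoff and refuses
  zero vectors; the loss is evaluated as `log1p(exp(s_neg - s_pos))` for
  stability; constant clips z-score to zero by convention.
* Instance/layer norm use ε = 1e-5; Adam uses ε = 1e-8.
* Chance F1 for the significance tests is estimated by permuting
  predicted labels (default B = 1000, seeded), keeping both margins of
  the confusion matrix — per-class chance depends on prevalence *and*
  predictor bias, so a flat 1/m is generally wrong (a `1/m` fallback is
  accepted via the `chance` argument).
* The per-class tests are one-sided (greater than chance), per fold,
  Benjamini–Hochberg corrected across classes; zero-variance folds give
  p = 0 above chance and p = 1 otherwise.

## Known limitations

* The engine is CPU-bound and single-threaded beyond BLAS; it is sized
  for method research on simulated volumes, not for full-resolution
  (80×96×88) cohort studies.
* Pretraining at desk scale is run far short of convergence; the suite
  asserts orderings (separation, transfer benefit), not effect sizes.
* The simulator's noise model is AR(1) + polynomial drift only.
* Subject-level cross-validation assumes subject ids are honest; nothing
  can detect the same person appearing under two ids.
* The t-test over per-fold F1 treats folds as exchangeable units (the
  usual practice, with few folds); per-subject units would be the
  conservative alternative.
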