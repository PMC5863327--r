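---
title: "deepTiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deepTiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `deepTiles` computes, which knobs matter,
what the synthetic generator does and does not emulate, and the design
decisions taken where the method description left genuine freedom.

## 1. The pipeline

The package classifies 32 × 32 × 3 RGB tiles into benign vs. malignant
(malignant is the positive class everywhere). A run consists of

1. *data*: a labelled tile collection — read from disk
   (`loadImageDirectory()`) or drawn from the synthetic generator
   (`generateSyntheticTiles()`);
2. *optional colour quantization* (`quantizeTiles()`): each tile's
   pixels are clustered as independent RGB triples and replaced by
   their centroid/mode colours;
3. *stratified split* (`stratifiedSplit()`, default 30 % held out);
4. *network training* (`buildModel()` + `trainSoftmax()`);
5. *optionally* a linear SVM decision head fitted on the trained
   network's penultimate features (`fitSvmHead()`);
6. *evaluation* (`confusionCounts()`, `metricReport()`).

`runExperiment()` chains the stages with per-stage logging and writes
CSV metrics, learning-curve PNGs and a JSON manifest; `runGrid()` and
`sweepExperiments()` organise the arm × model × decision grid and the
K / bandwidth / (TS, ID) sweeps.

## 2. Clustering transforms

Pixels are clustered in **colour space only** (no spatial
coordinates). This choice makes the Mean-Shift bandwidth meaningful on
the normalized [0, 1] colour scale — the default 0.2 is a fifth of the
colour-cube edge — and makes the transform a pure palette reduction,
which is what the quantized tiles look like. Each tile is fitted
independently; a corpus-wide palette would couple tiles and is not
what a per-image structure-discovery step intends.

**K-Means** is classic Lloyd: seeded k-means++ initialization,
nearest-centroid assignment (Euclidean), mean update, stop when the
largest centroid movement drops below `tol` (default 1e-4) or after
`maxIter` (default 300) iterations. Empty clusters are re-seeded at
the point farthest from its assigned centroid. The per-iteration
inertia trace is returned; it is non-increasing by construction and
the test suite asserts that on every fit it exercises.

**Mean-Shift** uses the flat (uniform) kernel: a seed is replaced by
the mean of all points within `bandwidth` until it moves less than
`tol`. Seeds are the occupied cells of a bandwidth-sized grid (their
point means), which is deterministic given the input order and fast on
the 1024 pixels of a tile. Converged modes closer than `bandwidth / 2`
are merged, earlier seed wins.

*A subtlety:* with the `bandwidth / 2` merge rule, surviving modes can
sit between `bandwidth / 2` and `bandwidth` apart. Re-quantizing such
an output moves mass again, so exact idempotence of the transform only
holds when the fitted palette is separated by more than the bandwidth —
which is the regime the transform is meant for (distinct tissue
colours), and the regime in which the test suite asserts idempotence.

## 3. The three architectures

All convolutions are 3 × 3, stride 1, zero-padded by one row/column
per side ("same"), so 32 × 32 feature maps stay 32 × 32; all poolings
are non-overlapping 2 × 2 (max by default, average available), halving
each spatial dimension. Convolution is implemented as
cross-correlation, the deep-learning convention; under learned kernels
the two are flip-equivalent, so nothing observable depends on it.

* **Model 1 (CNN)**: C1 → C2 → P1 → C3 → P2 → C4 → P3 → C5, spatial
  chain 32, 32, 16, 16, 8, 8, 4, 4. Only C5's width (16 maps) is fixed
  by the architecture's 256-feature flatten; C1–C4 widths default to
  16 as well (uniform with the one stated width) and are configurable
  via `modelSpec(convMaps = ...)`. Flatten → 25 % drop-out → decision
  layer.
* **Model 2 (LSTM)**: the flattened 3072-vector is reshaped
  **row-major** into TS steps × ID features (TS · ID = 3072 enforced
  with an error naming both factors). L-1 is a 42-unit LSTM returning
  sequences. The second recurrent block must contribute the parameter
  mass of *two* 42-unit LSTM layers for the analytic totals to
  reproduce the published six-row table exactly (58 280 … 40 808, with
  the finite-difference law ΔP = 4 · 42 · ΔID between consecutive
  rows). Two realizations with identical counts are provided:
  a **bidirectional** 42-unit layer with summed directions (default —
  it keeps "two LSTM layers" and "42 output neurons" literally true)
  and a **stacked** pair of 42-unit layers (`l2Kind = "stacked"`).
  Which the original experiments used cannot be determined from the
  totals alone. Then drop-out, dense 22 (ReLU), decision layer.
* **Model 3 (CNN-LSTM)**: C1–C3 (default 32 maps each, configurable),
  P1, flatten (8192), dense 512 (the bottleneck that becomes the
  sequence, TS · ID = 512), an LSTM, dense 65 (ReLU), drop-out,
  decision layer. The hybrid LSTM's width is unstated in the source
  description; the package defaults to 42 units, matching Model 2's
  stated width.

No default (TS, ID) pair is assumed for models 2 and 3 —
`modelSpec()` and the CLI require them explicitly, because no single
pair is distinguished as the headline configuration.

### LSTM gate conventions

The cell follows the standard form: candidate `tanh`, input / forget /
output gates logistic,
`c_t = c_{t-1} ⊙ f_t + cand_t ⊙ i_t`, `h_t = tanh(c_t) ⊙ o_t`.
(The source description swaps the *names* of the candidate and the
input gate — its "i_t" carries the tanh — but the algebra is the
conventional cell, so that is a naming difference only.) Per layer the
parameter count is `4 (h (d + h) + h)`; `lstmParamCount()` exposes the
formula and `countParameters()` verifies it against the actual
tensors.

### Activations

Sigmoid, tanh, ReLU and leaky ReLU are implemented in their standard
forms (`activation()`). Two printed formulas in the source material —
tanh as `2σ(x) − 1` (missing the doubled argument) and leaky ReLU as
`σ(x) + β ReLU(x)` — are algebraically not the named functions; the
package implements the standard definitions. The architectures only
use ReLU internally, so no result depends on this correction.

## 4. Decision layers and training

**Softmax head.** The two end-layer scores give
`ȳ_k = exp(F_k)/Σ_j exp(F_j)`; the loss is `−ln ȳ_true`, stabilized by
log-sum-exp (the source is silent on overflow). The decision is the
argmax of `ȳ` — equivalent to comparing the per-class losses. An exact
tie yields **benign**, deterministically: the no-disease label is the
conservative default, and the same rule applies to a zero SVM margin.

**Training.** Optimizer, learning rate and batch size are not part of
the method description; the package defaults to Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e-8), learning rate 1e-3, batch 32 —
standard, stable choices for networks of this size. `TrainConfig`
holds all of them. Weights are Glorot-uniform, seeded; drop-out uses
inverted scaling and is inactive at evaluation time (two evaluation
passes are bit-identical). Per epoch the history records train/test
accuracy, mean loss and MCC — the three learning-curve panels
`plotHistory()` draws. The nominal epoch budget of the method's
published experiments is 500 (`trainConfig()`'s default); examples and
tests use far fewer because their synthetic task saturates quickly.
Training aborts with a diagnostic on a non-finite loss. No
class-weighting or resampling is applied to the imbalanced data — the
method under study applies none — and no early stopping is used.

**SVM head.** The method description is ambiguous between end-to-end
hinge training and a post-hoc SVM on extracted features; the phrase
"after extracting features" motivates the default **two-stage**
regime: train with the softmax head, then fit a linear soft-margin SVM
(e1071/libsvm, `cost = C`, default C = 1, plain hinge) on the
penultimate activations with malignant = +1. The orientation of the
fitted hyperplane is normalized so that a positive margin always means
malignant. An end-to-end hinge mode is available as
`trainSoftmax(..., loss = "hinge")`. `svmObjective()` evaluates the
primal objective independently of the solver, which the tests use to
compare the fitted solution against a brute-force grid minimization.

## 5. The synthetic generator

`generateSyntheticTiles()` emulates the statistical skeleton of the
magnification-graded benchmark collections:

* **class imbalance** — labels are Bernoulli with
  `malignantFraction = 0.686` by default (the benchmark's roughly 70 %
  malignant prevalence);
* **two colour populations** — benign tiles get a light pink-ish
  background (default mean (0.85, 0.62, 0.74)), malignant tiles a
  darker purple-ish one ((0.52, 0.33, 0.58)), each jittered per tile
  by ±`colorSpread` (default 0.04);
* **nucleus-like texture** — a Poisson number of dark elliptical blobs
  (means 6 benign / 14 malignant), semi-axis 2–5 px, with malignant
  blobs more elongated (axis ratio 0.30–0.90 vs. 0.75–1.00) —
  mimicking higher nuclear density and pleomorphism;
* **sensor noise** — additive Gaussian noise (`noiseSd`, default
  0.02), clamped to [0, 1].

With `noiseSd = 0` the default palettes are disjoint and a pixel-mean
threshold classifier separates the classes perfectly — the test suite
uses that oracle to certify the dial before asking a network to learn
the task. What the generator does **not** emulate: real staining
variability, tissue morphology beyond blobs, magnification-dependent
texture, patient-level correlation between tiles, or any overlap
between the class distributions. A network passing the synthetic tests
is therefore shown to *optimize correctly on a learnable task*, not to
reach any particular accuracy on real histopathology; the published
benchmark numbers require the external image collection and 500-epoch
runs and are deliberately not asserted anywhere in the package.

## 6. Numerical choices and degenerate inputs

* K-Means: `tol = 1e-4` on centroid movement, `maxIter = 300`,
  k-means++ with duplicate-safe weighting (all-zero distance weights
  fall back to uniform sampling), empty-cluster re-seed at the
  farthest point. An image with ≤ K distinct colours is a zero-inertia
  fixed point.
* Mean-Shift: same `tol`/`maxIter`; window membership is `≤ bandwidth`;
  a constant image yields one mode equal to that colour.
* MCC: computed with a single square root of the exact cell-sum
  product and clamped to [-1, 1] against last-bit rounding; a zero
  denominator (degenerate margins) reports 0 in the learning curves,
  while `metricReport()` refuses inputs lacking an actual positive or
  negative. Undefined precision (no positive predictions) is reported
  as 0 with an explicit flag and warning.
* Splits: per class, `round(n_class · testFraction)` test members,
  clipped so both parts keep ≥ 1 of each class; classes of size < 2
  are an error.
* Resizing: bilinear, aspect ratio not preserved (a 760 × 460 source
  maps directly onto 32 × 32); grayscale images are replicated to
  three channels; intensities live in [0, 1] (bandwidths on any other
  scale would be meaningless).
* Seeds: one integer per run fans out to per-stage seeds (generator,
  clustering, split, initialization, batching) via a fixed mixing
  function kept below 2³¹, so no stage's randomness depends on another
  stage's consumption.

## 7. Problem sizes in the tests

The suite certifies the heavy end-to-end contract on 400 noise-free
synthetic tiles, 50 epochs, Model 1 — the smallest configuration at
which the optimization reliably saturates the separable task — and
exercises the full 18-cell grid at 40 tiles / 2 epochs, where only the
structure of the result table (not its values) is the point. Parameter
counting, shape chains, metric identities and clustering recovery are
exact or near-exact checks and run at toy sizes. The exhaustive metric
cross-check enumerates every confusion matrix up to n = 40.

## 8. Known limitations

* Pure-R training is CPU-bound: ~5 s/epoch at 400 tiles for Model 1.
  The implementation favours transparency (every gradient is ordinary
  R linear algebra, verified against numerical differentiation) over
  speed.
* Mixed and gated max-average pooling variants are not implemented
  (the architectures use max pooling; average pooling is available).
* No ROC/AUC, no patient-level aggregation, no augmentation or
  transfer learning; splits are tile-level, not patient-disjoint.
* The SVM head is linear only, matching the margin objective it
  implements.
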