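---
title: "Methods: ultrasound sex classification with sonosex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultrasound sex classification with sonosex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sonosex` is an end-to-end pipeline for classifying abalone sex from
transverse gonadal ultrasound frames. This vignette documents the models,
the tunable parameters and their defaults, the numerical conventions, and
the design decisions taken where the problem left genuine freedom. It
states no empirical result that the test suite or acceptance script does
not itself compute.

## The classification problem

A transverse ultrasound of an abalone shows a bright specimen region on a
near-black water background. Inside the specimen, the digestive gland
appears as a cone-shaped region and the gonad as a thin, higher-echogenicity
band enveloping that cone. Sex differences are subtle: band geometry and
echotexture differ between males and females, with no reliably localized
marker. Two statistical facts dominate the analysis design:

1. **Frames of one animal are strongly correlated.** Operators capture
   several frames per animal in one session; anatomy is fixed and only
   probe position and speckle vary. Any split that ignores individual
   identity therefore leaks near-duplicates across partitions and inflates
   apparent accuracy. All partitioning in this package is at the
   individual level, and `check_leakage()` audits any assignment.
2. **Speckle.** Ultrasound carries multiplicative interference noise that
   masks texture cues. This motivates the reverse ("double compression")
   CNN family, and the phantom generator treats speckle as a first-class
   parameter.

## The synthetic phantom generator

No public abalone ultrasound corpus exists, so the package ships a
generator whose output has the statistical structure the analysis assumes.
It is first-class, tested code, not a fixture.

**Latent anatomy per individual.** `sample_individual()` draws one
`phantom_spec` per animal — ellipse center/axes, cone apex, half-angle and
length, gonad-band thickness fraction, band/gland/coelom echogenicities,
band texture shape, and a per-animal overall gain. Every frame of that
animal is rendered from this one spec, which is precisely what makes
frame-level splits leaky. The same (sex, size class, seed, index) always
yields a bit-identical spec: all randomness flows from one integer seed
through counter-based substreams keyed by role, individual and frame.

**Rendering.** `render_frame()` composes background (intensity 2, strictly
below the ROI threshold of 5), coelom, gland cone, and the band as a ring
of the spec's thickness hugging the cone; applies per-frame translation
jitter and a ~1% axis-scale jitter (probe repositioning); multiplies
specimen pixels by unit-mean gamma speckle with shape `speckle_shape`
(default 6; `Inf` disables noise — the standard multiplicative
idealization of ultrasound speckle, chosen because it has controllable
variance and a Rayleigh-like look); then applies defects; then the device
overlay. The sampled per-frame geometry is attached to the returned image
so tests can reconstruct exact region masks via `phantom_masks()`.

**Sex effect encoding.** At `sex_effect = 1`, females get a thicker
(+0.05 fraction), darker (−12 intensity), higher-contrast (texture shape
−3) band; males the mirror image. These magnitudes are configuration
parameters, not biological claims — the real literature gives no
quantitative echotexture description, so effect sizes are free parameters.
`sex_effect = 0` makes the F and M parameter distributions identical,
which the tests verify by two-sample location tests and by checking that
the baseline cannot beat chance on unseen individuals. A separate
`gain_delta` (default 0) adds a sex-linked overall-brightness offset; it
exists so a *linear-in-pixels* effect can be switched on for the property
test that a linear classifier learns linear signals. With `gain_delta = 0`
overall brightness carries no sex information.

**Defects and overlay.** Echo ghost = an attenuated shifted copy of the
specimen added back (the simplest realization of a shell-reflection
artifact); missing anatomy = band *and* gland rendered at coelom intensity
(the criterion is absence of identifiable gonad/digestive-gland anatomy);
truncated field of view = the specimen shifted off a corner so the borders
cut it. The overlay is a constant frame of configurable width with an
optional burned-in "text" band of random bright dashes below the top
border. Clean specimens are guaranteed to sit inside the field of view
(axis and center draws are clamped at ±2 SD), so defect detectors can be
conservative without false positives.

**What the generator does not emulate:** beamforming, depth-dependent
attenuation, refraction and shadowing, real device fonts, and true
biological texture. Passing tests on phantoms demonstrate that the
*pipeline machinery* is correct — leakage-free splitting, detector logic,
optimizer behavior, metric arithmetic — not that any accuracy level
transfers to real animals.

**Default study conditions:** 22 individuals per sex (a full large-size
cohort), 5–8 frames per individual (deliberately uneven), canvas 128×160,
speckle shape 6, `sex_effect = 1`. Chosen once, up front; the tests use
smaller cohorts where statistical power permits.

## Preprocessing conventions

- **Binarization is strict**: foreground is intensity **> 5**; tie pixels
  at exactly 5 are background ("dark background" is an inequality with the
  threshold on the background side).
- **Connectivity is 8-neighbor**, implemented in C++ (BFS flood fill); the
  ROI is the bounding box of the largest-area component, with equal-area
  ties broken toward the lexicographically smallest (row0, col0) — fully
  deterministic.
- **Coordinates** are 0-based; boxes carry an inclusive origin plus
  explicit height/width, avoiding half-open ambiguity at the interface.
- **Overlay stripping** (`"auto"`) detects the maximal constant-intensity
  margin per side and removes a configured text-band height below the top
  border. An overlay-free image is returned unchanged.
- **Padding** defaults to the dataset-wide maximum height/width with a
  center anchor (the source analyses leave target dimensions unstated;
  max-dims is the smallest lossless choice), overridable.
- **Quality control** runs on overlay-stripped full frames, *before* ROI
  cropping, because the truncation criterion inspects the image borders.
  The three detectors are engineering proxies for what was originally a
  visual inspection step: (a) ghost = secondary peak prominence of the
  spatial autocorrelation beyond a 10-pixel lag (threshold 0.085 —
  measured clean frames stay below 0.06, ghosted frames exceed 0.11);
  (b) missing anatomy = (p98 − p30)/p30 contrast of 5×5-box-smoothed
  specimen pixels (threshold 0.40 — clean frames measure ≥ 0.5,
  anatomy-free frames ≤ 0.28); (c) incomplete capture = foreground
  covering ≥ 10% of at least two image borders. Thresholds are set with
  wide margins on both sides so the filter is conservative — it fires
  only on clear defects, and borderline frames are retained. Detectors see
  pixels only, never labels, so quality control cannot leak sex
  information.

The filename grammar
`<ID>_<location>_<sex>_<size>_<YYYYMMDD>_<frame>.png` is a repository
convention (the original naming scheme is undocumented); parsing and
formatting round-trip, and the individual identity key is
(ID, location, sex, size class).

## Partitioning and balancing

`assign_splits()` draws `n_val_per_sex` then `n_test_per_sex` individuals
of each sex uniformly without replacement (defaults 4 and 4); the rest
train. On a 22 F + 22 M roster this leaves 28 training individuals, 14 per
sex. Frame-level proportions are whatever the uneven per-animal counts
imply — the individual-level constraint has priority over hitting an 80/20
ratio.

`balance_training_set()` tops up under-represented training individuals
with offline-augmented copies of their own frames until each has
`min(target, cap)` frames; `"auto"` targets the current per-individual
maximum. Whether the original analysis balanced per-individual or
per-class counts is not recoverable; per-individual is the default and
both are reachable through configuration. Source frames are cycled in
filename order (deterministic), originals are never removed, augmented
rows carry a `synthetic` flag, and balancing runs strictly after split
assignment so no augmented copy can cross splits. Validation and test are
never augmented.

## Augmentation

Offline (balancing): rotation uniform in ±15°, zoom in ±20% (output dims
preserved), brightness and contrast factors in 1 ± 0.10. Train-time:
horizontal flip with probability 0.5; brightness/contrast/saturation/hue
jitter of 0.40/0.70/0.70/0.015 in the printed order of those defaults;
rectangle erasure with probability 0.4 (area 2–20% of the image,
log-uniform aspect in [0.3, 3.3], filled with 0); translation up to ±10%
per axis. Saturation and hue jitter are exact no-ops on zero-saturation
grayscale; the parameters are retained for fidelity to the stated policy
and documented as such. Geometric ops use bilinear interpolation with zero
fill (ultrasound background is black). Every operator is a pure function
of (image, params, seed).

## The linear baseline

Frames are resized to 64×64 (bilinear) and flattened row-major to 4,096
features. Standardization uses training-set means/SDs only; PCA is fitted
once on the training matrix at the largest candidate dimension and each
candidate `k` reuses its leading (nested) components. The grid crosses
C ∈ {0.001, 0.01, 0.1, 0.5, 1, 3, 5, 7, 10, 15, 20, 50, 100}, penalty ∈
{L1, L2}, solver ∈ {coordinate (glmnet, single lambda = 1/(C·n)), newton
(ridge-IRLS, tolerance 1e-4, max 5,000 iterations)}, and k ∈
{5, 10, 20, 30, 50, 75, 100} — 364 candidates. The newton solver supports
only L2; invalid pairs are enumerated, flagged, and skipped rather than
raised, mirroring ordinary grid-search practice. Class imbalance is
handled by inverse class-frequency loss weights. Selection maximizes
validation balanced accuracy (mean per-class recall); ties break toward
parsimony — smaller k, then smaller C, then L2 before L1. The positive
class is M (alphabetical F = 0, M = 1) with decision threshold 0.5, a
score of exactly 0.5 labelling M. The test partition is untouched during
search.

## The CNN families

Blocks are VGG-style: `convs_per_block` (default 2) 3×3 stride-1 pad-1
convolutions with ReLU, then one 2×2 max pool. The canonical channel
schedule is 512-256-128-64; size variants S/M/L take 2/3/4 blocks,
truncated from the high end (S = 128-64, M = 256-128-64, L = all four) —
the variant depths are a repository convention. The reverse family uses
the schedule as-is (strictly decreasing); the forward family is its mirror.
Exactly one dropout stage sits at the end of the convolutional stack,
immediately before flattening; a dense head (default one layer of 64)
feeds a single sigmoid output trained with binary cross-entropy.

Training (all in-package: Rcpp im2col/col2im/max-pool kernels, BLAS matrix
products, backpropagation verified against central-difference gradients):
minibatch SGD-with-momentum (0.9) or Adam (0.9/0.999); shuffling, dropout
masks and augmentation all derive from the config seed, so runs are
bit-reproducible. Early stopping monitors validation loss from
`monitor_start_epoch` (default 100) with `patience` (default 500) —
paper-scale values; desk-scale runs here use 300 max epochs and patience
around 10–30. The stated "validation loss (0.70 minimum)" convention is
read as a checkpoint quality gate: the retained weights are those of the
epoch with the lowest validation loss *among epochs below 0.70*, and no
checkpoint is ever taken above the gate (0.70 sits just above the ~0.693
chance-level binary cross-entropy, so the gate admits anything better than
chance). If no epoch passes, the final weights are returned flagged.
The optimizer set for hyperparameter grids is {SGD momentum, Adam}, the
two standard choices. Warm starts load a donor checkpoint's weights and
require an exactly matching architecture.

**Desk scale.** The acceptance-grade experiments here run width-scaled
networks (`width_scale` 1/8 or 1/16 of the canonical channel counts) at
input 64 on cohorts of 10–22 individuals per sex — sizes chosen so the
full suite trains several networks in minutes on one core while preserving
the architectural shape (schedule monotonicity, double compression,
dropout placement). The family-comparison benchmark fixes a weak-texture,
high-speckle regime (thickness delta ≈ 0, echogenicity/texture deltas
positive, speckle shape 3) — the regime where channel compression is
hypothesized to matter — matches parameter budgets by adjusting dense-head
widths (reverse 64, forward 32), and compares mean unseen-individual test
accuracy over five fixed split seeds, asserting the reverse family is no
more than 2 points behind. The magnitude of any reverse advantage on real
abalone images cannot be verified from synthetic phantoms and is left
open.

## Evaluation

`confusion()` uses truth rows and predicted columns over (F, M);
`metrics_from_confusion()` computes accuracy, per-class precision, recall
and F1, reporting zero-denominator ratios as `NaN` with an `undefined`
flag rather than silently zeroing them. F1 is included even where only
precision/recall were originally reported — a harmless superset.
`leakage_inflation_experiment()` packages the motivating control: twin
classifiers on frame-level versus individual-level splits of matched
holdout size, the default classifier being a fast PCA + ridge-logistic
baseline, reporting per-strategy mean accuracy and the inflation gap.

## Feature diagnostics

`extract_activations()` returns per-channel post-ReLU maps of any
convolution layer plus an overlay (channel mean, min-max normalized,
bilinearly upsampled, alpha-blended). `pooled_features()` global-average-
pools the last convolutional activation — the default feature space for
the diagnostics; which layer originally fed the clustering analysis is
unstated, so the layer is configurable. `select_k()` clusters with
`stats::kmeans` (10 seeded restarts), selects K by silhouette argmax and
reports the elbow K alongside; the elbow is formalized as the maximum
second difference of the WCSS curve, anchored at K = 1 (total scatter) so
a bend at the smallest candidate is detectable; when the two criteria
disagree, silhouette wins and the disagreement is recorded. Clustering
defaults to the top-2 PCA scores in the experiment runner, with
full-feature clustering available. t-SNE is implemented exactly (O(n²)):
per-point Gaussian bandwidths calibrated to the target perplexity by
bisection, symmetrized affinities, Student-t low-dimensional kernel, KL
gradient descent with early exaggeration (×4 for 100 iterations) and
momentum (0.5 → 0.8 at iteration 250) — no R t-SNE package is available
in this stack, and at the few hundred frames involved the exact method is
preferable anyway. The known dissociation — classifiers can be accurate
while intermediate features barely cluster (silhouette ≈ 0.1) — is
reproduced as a property: overlapping-class features with linear accuracy
above 0.8 score silhouette below 0.15.

## The experiment runner

`run_experiment()` executes simulate → preprocess → split → balance →
baseline → CNN → evaluate → interpret from one `experiment_config()`,
writing a verbatim config copy before any stage runs, a JSON-lines log
with per-stage seeds and durations, and per-stage `.done` hashes for
resumable reruns. The evaluate stage is the only one that reads test-split
frames; the test suite enforces this with a tripwire (test files are
deleted and the training-side stages must still succeed). The package's
functions and this runner are the interface; there is no separate shell
executable.

## Known limitations

- Phantom realism is deliberately minimal; absolute accuracies on
  synthetic data say nothing about real animals.
- The quality detectors are calibrated to the generator's defect
  renderings; real ghost artifacts and real missing-anatomy frames are
  more varied.
- The CNN engine is CPU-bound R/Rcpp: correct and reproducible, but not a
  platform for paper-scale (224-pixel, 968-model) sweeps.
- Small-animal imagery is supported by the generator (`size_class =
  "small"`) and by warm starts, but the shipped experiments use the large
  class only, matching the scope of the analysis being reproduced.
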