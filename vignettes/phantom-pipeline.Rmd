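---
title: "Patch-based phantom mammogram classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based phantom mammogram classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammopatch)
```

## The problem and the pipeline

Screening mammograms are large, low-contrast images in which malignant
masses differ from benign ones chiefly in local texture and in the
irregularity of their margins. `mammopatch` implements a patch-level
classification pipeline for such images: each image is tiled into small
fixed-size windows, every window is labeled by the class occupying the
majority of its area in a ground-truth mask, and a classifier is trained on
fused deep and handcrafted descriptors of the windows. Working at patch
level concentrates the classifier on localized structure and turns one
annotated image into dozens of training examples.

Because real screening archives are large, access-restricted downloads,
the package ships a synthetic phantom generator that reproduces the
*structure* of the problem — textured background, bright lesion, mask,
binary label — so the entire pipeline is exercised end to end by code
alone. All results quoted in this vignette and in the test suite are
computed on phantoms, and they validate the machinery, not clinical
performance on real mammograms.

## The phantom generator

A phantom is band-limited Gaussian noise (white noise low-pass filtered
with a sigma = 4 px Gaussian) affinely mapped to mean 120 and sd 25 on the
8-bit scale, which gives a breast-tissue-like mid-gray mottle. A lesion is
a bright ellipse whose boundary radius is modulated as

r(theta) = r0 * (1 + rho * sin(5 theta + phi)),

with `rho` the `boundary_roughness` and `phi` a seed-derived phase. A
smooth boundary (`rho = 0`) defines the benign class; a perturbed one
(`rho` drawn in 0.25–0.45) defines the malignant class, mimicking the
irregular margins radiologists associate with malignancy. Pixels inside
the boundary are brightened by `intensity_gain` (default 1.6, which keeps
lesion interiors clearly above background after clipping to [0, 255]) and
written to the mask for *both* classes — masks mark lesions, labels mark
malignancy, exactly as in annotated screening data.

Default lesion axes are drawn so the lesion area is about one 64 px patch
(semi-major 34–44 px, semi-minor 24–34 px at the 256 px study size,
scaled proportionally for other frames). This choice makes the
majority-region rule meaningful: a typical malignant phantom contributes
one or two malignant patches rather than none (lesions much smaller than
a patch never reach 50% coverage) or dozens (lesions much larger than the
frame). One lesion per image; multi-lesion phantoms are out of scope.

What the phantoms deliberately do **not** model: X-ray physics, pectoral
muscle and skin-line anatomy, calcification clusters, scanner noise
statistics. Passing tests therefore demonstrate correctness of the
pipeline's operations and the learnability of boundary texture, nothing
more.

## Preprocessing

Images are resized bilinearly (output clipped to the input intensity
range), normalized by exact division by 255 — with a range guard so
normalizing twice raises an error rather than silently shrinking the data
— and contrast-enhanced with CLAHE. The CLAHE clip limit (2.0) and tile
grid (8 x 8) are the common defaults for mammography-scale images; the
enhanced output is kept in [0, 1] by construction and not re-normalized.

Augmentation (rotation within ±30 degrees, zoom 0.8–1.2, horizontal flip,
translation within 10%) is implemented as a single inverse-mapped affine
resample with bilinear interpolation and zero fill for exposed borders
(matching the dark mammogram surround). Identity parameters reproduce the
input bit for bit, and parameters outside the training ranges are
rejected unless explicitly overridden.

The headline split is 70-30 at image level, stratified and seeded. The
validation set used for hyperparameter fitness is carved from the
training split (80/20), keeping the 70-30 figure intact. Feature
standardization uses the population (n-denominator) standard deviation,
is fitted on training rows only, and drops zero-variance columns with a
warning (rare LBP bins never observed in training produce such columns).

## Patch extraction and labeling

Patch grids are defined by patch size and step. With step equal to patch
size only complete windows are emitted — an H x W image yields
`floor(H/P) * floor(W/P)` patches, so the 256 px study image with 64 px
patches yields exactly 16. With smaller steps the windows overlap; starts
advance in multiples of the step until the window reaches the image edge,
and the trailing window in each dimension is clamped to the frame, which
can make edge patches smaller than nominal. Such patches are flagged and
zero-padded to full size before feature extraction so downstream feature
vectors have fixed length. Coordinates are 0-based, row-major, half-open;
a unit test pins the correspondence to R's 1-based closed indexing.

A patch's `malignant_area_fraction` is the share of malignant-mask pixels
in its window; the patch is malignant when the fraction reaches the
threshold (default 0.5). Ties at exactly the threshold are labeled
malignant — favoring sensitivity, since false negatives are the costly
error in screening. Because masks mark lesions in both classes, the
malignant mask is the lesion mask gated by the image label: lesion
patches of benign images stay benign.

## Features

**LBP.** Eight radius-1 neighbors, visited clockwise from the top-left,
are thresholded against the center with `s(x) = 1` iff `x >= 0` applied
to `center - neighbor`, and the bits packed into a code in [0, 255]. Note
the sign convention: the canonical LBP literature thresholds
`neighbor - center`; both are available (`convention` argument), the
center-minus-neighbor form being the package default. The two differ only
at strict inequalities (a constant patch maps to code 255 under the
default, 255 under the canonical too since `s(0) = 1` either way, but
asymmetric neighborhoods differ). Per-patch aggregation is a normalized
256-bin histogram — the standard texture descriptor; because codes depend
only on intensity differences, the histogram is invariant under positive
affine intensity maps.

**Hu moments.** Seven invariants of scale-normalized central moments,
invariant to translation, rotation and scale of the intensity pattern.
Each is reported as `sign(h) * log10(|h| + 1e-30)` for numeric stability,
since raw invariants span many orders of magnitude. Tolerances observed
on the phantom fixture suite: translation is exact (central moments are
translation-invariant by construction), 90-degree rotation is an exact
raster permutation (< 1e-6), and 2x nearest-neighbor scaling agrees to
5e-2 on the log scale (discretization-limited).

**Edge statistics.** A Canny detector (Gaussian smoothing at sigma = 1,
Sobel gradients, non-maximum suppression over four quantized directions,
double-threshold hysteresis in which weak edges survive only in
8-connected components containing a strong edge) produces the edge map.
The map is summarized by three fixed scalars: edge density, 8-connected
component count, and mean gradient magnitude. Hysteresis thresholds
default to the 90th percentile of the suppressed gradient magnitudes
(high) and 0.4x that (low), adapting to per-patch contrast. Rough lesion
boundaries produce denser, more fragmented edge maps than smooth ones —
this is the main signal separating the two lesion classes.

**Deep features.** The deep-feature contract is a frozen backbone mapping
a fixed-size patch to the spatially pooled activations of its final
convolutional stage. The bundled `tiny_backbone()` is a small random
frozen CNN (stages of 3x3 convolution, ReLU, 2x2 max pooling, then global
average pooling), so the pipeline requires no downloaded weights; random
frozen convolutions act as generic texture projections. A large
pretrained residual network can be substituted by providing any object
with the same forward contract. **Fusion** is plain concatenation,
deep-then-handcrafted, with no rescaling at fusion time (standardization
is a separate, train-fitted step).

## Progressive cyclical training

The classifier bundled with the package is a small MLP over fused
features whose hidden layers form named groups (`block1`, ..., `head`).
Progressive training freezes early groups first: stage k of K trains the
head plus the last `n_groups - K + k` groups, so trainable sets are
nested and the final stage always trains everything. Epochs divide as
evenly as possible with the remainder on the final stage (50 epochs in 4
stages = 12, 12, 12, 14).

The learning rate follows cosine annealing with warm restarts:

LR(t) = LR_min + (LR_max - LR_min)/2 * (1 + cos(pi * T_cur / T_max)),

starting each cycle at `LR_max`, reaching `LR_min` at the cycle end, and
restarting. Two printed forms of this schedule circulate, one with the
ratio inverted (`T_max / T_cur`); that form is singular at the cycle
start and contradicts the described oscillation, so the standard form is
implemented, with an optional triangular (linear up-down) mode behind a
flag for the oscillation described in prose accounts. Defaults are the
study configuration: bounds 1e-5 and 1e-3, 50 epochs, batch 32, dropout
0.3, binary cross-entropy, Adam as the base optimizer with its step size
overridden every iteration by the schedule. `T_max` defaults to ten
epochs' worth of iterations when unset. Frozen groups receive no updates
at all — their parameters (and Adam moments) are bit-identical across a
stage, which the tests check by serialization.

Small-sample note: the 1e-3 upper bound is calibrated to
thousands-of-iterations runs. On tiny fixtures (hundreds of rows, tens of
iterations) Adam needs larger steps to converge, so the fixture tests and
the compact cross-validation default use bounds around 1e-4 to 1e-2;
same schedule, scaled to the problem.

## Swarm hyperparameter search

The tuner is a firefly-style population maximizer over a mixed search
space. Candidates live in unit-cube coordinates; continuous dimensions
decode linearly or log-uniformly, discrete ones by nearest-value
snapping. In each generation every candidate moves toward every brighter
partner by

x_i' = x_i + beta0 * exp(-gamma * r_ij^2) * (x_j - x_i) + alpha * delta_i,

with `r_ij` the Euclidean distance in unit-cube coordinates (so `gamma`
is scale-free across mixed dimensions) and `delta_i` uniform on
(-0.5, 0.5) per dimension. A move is kept only when fitness strictly
improves, making per-candidate fitness monotone — a greedy retention that
also bounds total evaluations by `N + N(N-1)G`. One published variant
prints the attraction inequality the other way around (the brighter
candidate moving toward the dimmer); standard semantics are the default
and the literal variant sits behind `literal_rule = TRUE`. Unstated
constants were fixed once: `beta0 = 1`, `gamma = 1`, `alpha = 0.1`,
N = 15, G = 20, with early stopping after 10 stagnant generations (an
artifact addition; the base procedure stops only at G).

Tuning fitness is the validation accuracy of a short proxy training run
with the decoded hyperparameters, using a fixed proxy seed so fitness is
a pure, reproducible function of the assignment. The best assignment is
rebuilt into a full-budget training plan.

## Evaluation

Confusion counts, accuracy, precision, recall and F1 follow their
defining formulas with malignant as the positive class; a zero
denominator yields `NA` plus a warning, never a silent zero. ROC-AUC is
the trapezoidal area with tied scores grouped, which equals the pairwise
concordance statistic — an O(n^2) oracle the tests verify to 1e-12.
Row-normalized confusion percentages sum to exactly 100 per true-class
row. Calibration uses 10 equal-width bins by default, omitting empty
bins. Cross-validation is stratified and seeded, refits the
standardizer and model per fold, and reports mean ± sd with 95%
percentile bootstrap intervals (2000 resamples) per metric. Metrics are
computed at patch level, the pipeline's unit of classification.

Class imbalance: with patch-level labeling, malignant patches are a few
percent of the total (one or two per malignant image against 14-15
background patches). Ranking quality (AUC) is therefore the robust
headline number; point metrics at the fixed 0.5 threshold can be
conservative (high precision, low recall) on small test sets, and the
decision threshold is exposed in the evaluation config for
sensitivity-oriented operating points.

## The end-to-end study and problem sizes

The default configuration — 200 phantoms at 256 x 256 (100 smooth-benign
and 100 rough-malignant, gain 1.6), 16 non-overlapping 64 px patches per
image, fused features (8 deep + 266 handcrafted), 70-30 image-level
split, 50 epochs — runs in about a minute on one CPU and reaches
patch-level test accuracy above 0.98 and AUC above 0.95; rerunning with
the same master seed reproduces the metric report byte for byte. These
sizes were chosen to exercise every stage at meaningful scale while
keeping a full run interactive; they are the sizes the test suite and
`scripts/acceptance.R` use.

## Numerical and degenerate-input choices

- Seeds: every stochastic step (phantom synthesis, splits, shuffling,
  dropout, swarm moves) draws from a seed derived deterministically from
  the master seed; no global RNG state leaks (`withr::with_seed`).
- Normalization guards: inputs outside [0, 255] (or [0, 1] after
  normalization) raise errors instead of being rescaled.
- Zero-variance features are dropped at standardization with a warning.
- All-zero images have no intensity centroid; moment computations raise
  an error rather than returning NaN.
- A constant patch has no gradient: the Canny stage returns an empty edge
  map (density 0, components 0) instead of thresholding noise.
- Patch grids larger than the image yield an empty, logged result in
  non-overlapping mode (an error would make exhaustive sweeps awkward);
  overlapping mode emits a single clamped window.
- NaN/Inf training loss aborts with a diagnostic naming the iteration.
- Swarm fitness failures score -Inf and are logged; optimization only
  errors when every initial evaluation fails.

## Interfaces

Stage functions are exported individually (`generate_dataset`,
`extract_patches`, `patch_features`, `train_classifier`,
`optimize_swarm`, `cross_validate`, ...), and `run_pipeline()` composes
them under a single config with per-stage caching keyed by an MD5 hash of
the canonicalized stage-relevant config subtree; `resume = TRUE` reuses
any cached stage whose key matches. A thin command-line front end at
`inst/cli/mammopatch.R` wraps synthesis, full runs, tuning and report
inspection; the remaining stages are driven through the R functions,
which are the primary interface.

## Known limitations

- Phantom realism is deliberately minimal (see above); no claim transfers
  to clinical data without retraining and revalidation.
- The bundled backbone is a random frozen projection, not a pretrained
  network; its features are weak alone and earn their keep only fused
  with the handcrafted descriptors.
- The MLP trainer is plain R; it is sized for feature vectors, not for
  training convolutional backbones end to end.
- Image-level aggregation of patch scores is provided only as a secondary
  report; thresholds for clinical-style image calls are not studied.
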