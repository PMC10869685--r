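---
title: "Dual-view mammography screening: model, losses, and triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-view mammography screening: model, losses, and triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvscreen)
```

## The screening problem

Population-scale mammography screening is limited by radiologist time. A
screening study produces four views — cranio-caudal (CC) and mediolateral
oblique (MLO) projections of each breast — and the radiologist's first task
is a binary call per breast: normal, or abnormal and in need of further
workup. `dvscreen` implements a decision-support pipeline for this setting:
a breast-wise abnormality classifier that reads both views jointly, a
suspicious-mass object detector, a fused binary decision, and a four-tier
priority queue that orders patients for review so that the most urgent
cases are read first.

Labels follow the BI-RADS reporting standard: category 1 (negative) is
treated as normal, categories 2–6 as abnormal. The screening-critical
metric is sensitivity (recall on the abnormal class) — a missed cancer is
far costlier than a false recall.

## The dual-view classifier

Each view is reduced to a feature vector by a backbone
(`v_cc = f(x_cc)`, `v_mlo = f(x_mlo)`, both of length *d*). Because the two
projections image the same tissue from different angles, the MLO features
are passed through a learnable linear transformation block

    v*_mlo = w^T v_mlo,        w ∈ R^{d×d}, no bias,

whose job is to map MLO feature space toward CC feature space. The
classification head is a sigmoid unit on the concatenation
`(v_cc, v*_mlo)` of length 2*d*. Training minimizes the combined loss

    L = α · CE + β · cos_loss,     0 ≤ α, β ≤ 1,

where CE is the binary cross-entropy of the head,

    CE = -(1/N) Σ [ y_i log ŷ_i + (1 − y_i) log(1 − ŷ_i) ],

and the cosine alignment loss pulls the transformed MLO vector toward the
CC vector in direction:

    cos_loss = 1 − (v_cc · v*_mlo) / (‖v_cc‖ ‖v*_mlo‖)  ∈ [0, 2].

The alignment term is auxiliary: it regularizes `w` toward a consistent
cross-view representation without carrying label information. Defaults are
`alpha = 1`, `beta = 0.1`, so classification dominates; `beta = 0` turns
alignment off entirely, and the package's tests confirm that a positive
`beta` strictly reduces the mean cosine distance between `v_cc` and
`v*_mlo` on held-out data.

Before feature extraction every view is standardized: right-laterality
images are mirrored left–right so the chest wall always sits at `x = 0`,
then resized to a square model input (aspect preserved, zero padding on
the side away from the chest wall). This makes the classifier see left and
right breasts identically; for an exact mirror pair the forward pass is
bitwise laterality-invariant.

### The backbone contract

The architecture treats the feature extractor as a contract: any
deterministic function from an image matrix to a fixed-length vector. A
large pretrained convolutional network fulfills it in a production
deployment. The package ships `grid_backbone()`, a deterministic
desk-scale extractor that divides the input into a `grid × grid` lattice
and emits each cell's mean and maximum intensity (`d = 2·grid²`, 72 for
the default `grid = 6`). Cell maxima respond strongly to compact bright
structures — exactly the mass-like signal the synthetic generator plants —
while cell means capture tissue layout. It is not a substitute for a deep
network on real mammograms; it is the smallest extractor that makes the
full training loop, the transform block, and both loss terms exercisable
and testable end to end.

### Optimization choices

Training uses minibatch Adam (β₁ = 0.9, β₂ = 0.999) on `w`, the head
weights, and the bias, with backbones frozen; gradients of both loss terms
are computed analytically and vectorized over the batch. Early stopping
monitors the validation combined loss with a patience of 10 epochs
(default) inside a 100-epoch cap, and the parameters at the validation
minimum are restored. `w` is initialized at the identity — a neutral prior
for a view-to-view mapping — and the head at zero, so an untrained model
outputs probability 0.5 exactly. Predictions inside the cross-entropy are
clamped at ε = 1e-7. A zero-norm feature vector makes the cosine loss
undefined; the package returns 0 for that sample with a warning rather
than penalizing a degenerate extractor output in an arbitrary direction.

The default learning rate is 3e-4, appropriate for fine-tuning a deep
backbone. The desk-scale configurations used in the package's own tests
pass `learning_rate = 0.05`: the tiny model is a shallow
few-thousand-parameter head over `[0, 1]`-scale pooled features, and Adam
needs a correspondingly larger step to traverse that landscape in tens of
epochs. This is a property of the model scale, not of the data.

## Detection, ensembling, and NMS

Detectors are pluggable contracts (image matrix → bounding boxes). Boxes
use 0-based, half-open pixel coordinates, origin top-left, x = column, and
carry one of six finding classes (suspicious mass, lymph node,
calcification, architectural distortion, skin thickening, nipple
retraction), an objectness score in `[0, 1]`, and a source-model tag.
Ensembling concatenates the outputs of several models and applies greedy
per-class non-maximum suppression (default IoU threshold 0.45, a common
detector default; the threshold is configuration, not a derived value).
Suppression is per class so a mass detection never silences an overlapping
lymph-node detection — a distinction that matters clinically. Ties in
objectness break toward the lower `(x_min, y_min)` corner for determinism.

The reference `blob_detector()` thresholds the image at the larger of an
intensity quantile (0.95) and an absolute floor (0.7), labels connected
components, and emits one box per component of at least 20 px with
objectness equal to the component's mean intensity. It boxes the bright
*core* of a mass: for a Gaussian-profile blob the core above the floor is
roughly two thirds of the ground-truth 2σ extent, so box agreement with
generated ground truth is evaluated at IoU 0.3 (the pipeline's operating
point) rather than the conventional 0.5 — average precision at both
thresholds is reported by the acceptance script. Externally trained
detectors enter bit-exactly through `yolo_file_detector()`, which reads
YOLO-format prediction files (`class cx cy w h conf`, normalized).

## The decision rule and priority queue

Per breast, the pipeline produces a classifier probability `p` and a
suspicious-mass objectness `s` (the maximum over both views — a finding
visible in one projection suffices). The binary decision is

    abnormal  ⇔  p > 0.5  OR  s ≥ 0.25,

with strict inequality on the probability ("exceeds") and inclusive on the
objectness ("0.25 or higher"). The disjunction is deliberate: it lets the
detector rescue classifier misses, which can only raise sensitivity (the
fused abnormal set is a superset of the classifier's) at some cost in
precision — the trade a screening tool wants. A conjunctive reading is
available via `logic = "and"` for comparison.

The review queue has four tiers: (1) detected suspicious mass, (2)
classifier-abnormal without one, (3) findings from the broader
all-abnormality detector only — these inform prioritization but never flip
the binary decision, since the wider finding classes are too
false-positive-prone to gate the call — and (4) nothing flagged. Breasts
sort by tier, then by descending `max(p, s)`, then by study id; a patient
inherits the best tier over their breasts.

## Evaluation

Abnormal is the positive class throughout. `classification_metrics()`
reports precision, recall, F1 and accuracy from a 2×2 confusion matrix;
ratios with a zero denominator are reported as 0 and flagged, keeping
means over cross-validation folds defined without hiding degenerate folds.
AUC-ROC uses the trapezoidal/Mann–Whitney definition (via pROC) and is
cross-checked in the tests against an exhaustive pairwise U-statistic
oracle. Detection average precision uses greedy score-ordered matching and
all-point PR interpolation, the modern detector-evaluation convention.

Cross-validation is grouped by study: a fixed-seed 20% study-level test
split is reserved first, then studies are shuffled and dealt round-robin
into k folds, so both breasts (and all four views) of a study always share
a fold and no study ever appears on both sides of a split — leakage is a
hard error, not a warning.

## The synthetic cohort generator

Every stage is testable offline against `generate_cohort()`, which emits
four-view studies with known ground truth. A breast is abnormal with
probability `abnormal_fraction` (default 0.3); abnormal breasts carry 1–3
Gaussian-profile bright blobs (radius 6–11 px, peak +0.5 intensity) at the
same distance from the chest wall in both views with independent
transverse jitter — mimicking how one physical mass appears in two
projections without modeling 3D geometry. The MLO view adds a pectoral
wedge (intensity 0.55) in the chest-wall corner; tissue sits at 0.45 on a
dark background with additive Gaussian noise (sd 0.02); right breasts are
rendered mirrored. BI-RADS is 1 for normal breasts and drawn from 2–5 for
abnormal ones with benign-skewed weights, matching how screening
populations skew. Determinism is per `(params, study_id, laterality)` via
a hashed seed, so any exam can be regenerated independently of generation
order, and identical parameters give bit-identical cohorts.

What the generator does *not* emulate: tissue texture and density
variation, mass margins and spiculation, calcification morphology,
positioning and exposure variability, or any correlation between BI-RADS
category and lesion appearance. Passing tests therefore demonstrate that
the pipeline's mechanics — losses, training loop, detection, fusion,
triage, and evaluation — are correct and that the architecture can learn a
planted, separable signal; they say nothing about accuracy on real
mammograms, which depends on a real backbone and real training data.

## Problem sizes and reproducibility

The package's test suite trains on cohorts of 40–250 studies (80–500
breasts) at 128 px resolution with the grid backbone — sizes chosen so the
full suite exercises every stage, including five-fold cross-validation, in
about a minute. The acceptance script runs the complete
generate → train → detect → screen → evaluate pipeline on a 150-study
cohort (300 breasts, 20% held out by study) in a few seconds, with every
random draw keyed to its `--seed` argument. All results it reports are
computed at run time from that pipeline.

## Known limitations

* The grid backbone is intentionally minimal; swapping in a stronger
  extractor only requires satisfying the `backbone()` contract.
* The DICOM reader covers single-frame uncompressed little-endian files
  (explicit or implicit VR) with per-image max normalization; compressed
  or multi-frame objects are rejected.
* The blob detector's boxes cover the bright core rather than the full
  lesion extent (see above), and its objectness is a mean intensity, not a
  calibrated confidence.
* Patient-level queueing uses the best breast tier; other hospital-policy
  orderings are easy to derive from the per-breast table.
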