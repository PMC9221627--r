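---
title: "Weighted box fusion and detection evaluation: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted box fusion and detection evaluation: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxrfuse)
```

`cxrfuse` covers the part of a chest-X-ray pneumonia-detection pipeline
that comes *after* network training: preparing images, filtering and
suppressing raw detector output, fusing the predictions of several
detectors into an ensemble, and scoring predictions against ground truth.
This vignette records the models it implements, the conventions it fixes
where the field allows several, and the design decisions that were
genuinely open.

## Box geometry

Boxes are continuous corner-form rectangles `(x1, y1, x2, y2)`, origin at
the image's top-left, with the half-open reading `[x1, x2) × [y1, y2)`.
Area is exactly `(x2 − x1)(y2 − y1)` whether coordinates are integral or
fractional — fused boxes are weighted means and are almost never integral —
and edge-touching boxes have intersection zero. The pixel-inclusive "+1"
area convention found in some older detection code is deliberately not
used; the choice is a documented convention, not something the fusion or
evaluation literature fixes. Degenerate boxes (`x2 ≤ x1` or `y2 ≤ y1`) are
rejected at construction, so every downstream operation is total on valid
boxes.

IoU — intersection area over union area — is the single agreement measure
used throughout: grouping member predictions during fusion, suppressing
duplicates in NMS, and deciding true positives during matching. The
conventional operating threshold in all three roles is 0.5.

## Input formats

Two exchange formats are supported. The RSNA challenge CSV dialect stores
one box per row (`patientId, x, y, width, height`, plus `score` — alias
`confidence` — and optionally `model` for predictions); a row with empty
coordinates declares an image with *no* boxes, and such negative images are
kept explicitly in the ground-truth universe because they contribute false
positives to evaluation. The packed one-row-per-image `PredictionString`
submission format is available write-side only. COCO-style JSON
(`images` / `annotations` with `bbox = [x, y, w, h]`) is read and written
with annotations carrying a `score` treated as predictions. Duplicate rows
are preserved on read: whether duplicates are meaningful is a filtering
decision, not a parsing one. Files are UTF-8 with `.` decimals; no locale
inference.

## Image preparation

Two steps, in order: percentile contrast stretching, then bilinear
resizing to 512 × 512.

*Contrast stretching* clips each image at the 1st and 99th percentile of
its own pixel values and rescales linearly to the output range (0–255 by
default). Percentiles use linear interpolation between order statistics
(R's default type 7) — the dominant convention, fixed here so results are
reproducible. Saturation is computed **per image**, not per dataset: the
per-dataset alternative would make one image's output depend on the batch
it arrived in. A constant image is returned unchanged. The operation is
monotone (pixel ordering is preserved), its output is confined to the
output range, and re-stretching an already-stretched image moves values
only marginally, because the clipped tails form plateaus at the bounds.

*Resizing* is plain bilinear resampling with the half-pixel-center mapping
`src = (dst + 0.5) · size_in / size_out − 0.5` and edge clamping, the
convention of mainstream imaging libraries. Aspect ratio is not preserved.
Interpolation order is a documented choice — nothing in the detection
pipeline depends on it beyond reproducibility. Since annotations must
follow their images, `scale_boxes()` applies the per-axis factors
`target / source` to box corners.

## Loss functions

The four losses are provided as standalone, vectorized numeric functions —
no gradients, no layers — so that their values can be verified by hand
arithmetic.

- **Categorical cross-entropy**: `−Σ_k y_k log ŷ_k` for a one-hot target,
  natural logarithm. All logarithms in the package are natural: base only
  rescales losses by a constant, and the focal-loss limit below holds in
  any base. Probabilities are clamped below at `1e-12` before the log.
- **Focal loss**: `−α_t (1 − p_t)^γ log p_t`, default `γ = 2` (the value
  that worked best for this detection task) and `α_t = 0.25` (the usual
  companion of `γ = 2` in dense detection; no single value is canonical,
  so it is exposed rather than asserted). At `γ = 0`, `α_t = 1` the loss
  *equals* cross-entropy on the true class — the package tests this to
  machine precision.
- **Focal Tversky loss**: `(1 − TI)^γ` with
  `TI = (Σ t g + ε) / (Σ t g + α Σ (1−t) g + β Σ t (1−g) + ε)` over the
  pixels of one class, defaults `α = 0.7`, `β = 0.75`, `γ = 4/3`. The
  stability constant defaults to `ε = 1e-7`; it makes the all-empty
  labeling score `TI = 1` (loss 0) instead of 0/0.
- **Smooth-L1**: `0.5 x²` for `|x| < δ`, `|x| − 0.5 δ` otherwise, `δ = 1`
  — the standard box-regression loss, with sum reduction by default as in
  box-coordinate regression.

Reductions (`mean`, `sum`, `none`) are explicit arguments wherever a loss
is vectorized.

## Confidence filtering, NMS, and the weighted averaging ensemble

Member predictions pass through three stages, mirroring how detector
output is post-processed in practice: a **strict** confidence filter
(score `> 0.9`; a score of exactly 0.9 is dropped — the boundary behavior
is tested), greedy per-image NMS at IoU 0.5 within each member, and then
fusion across members.

`fuse()` implements the rank-weighted averaging ensemble. Members are
ranked by validation mAP (best first) and weighted 1, 0.9, 0.8 — the
empirical rank weights; `rank_and_weight()` builds this configuration from
a named score vector, breaking ties by model id for determinism. Per
image, pooled records are visited in order of descending weighted score;
each unassigned record seeds a cluster, and a remaining record joins when
its IoU *with the seed* reaches the grouping threshold (0.5) and its model
is not yet represented — at most one record per member per cluster.
Testing against the seed rather than a running mean keeps clustering
deterministic and independent of join order. Each cluster with at least
`min_votes` contributors (default 1: the ensemble degrades gracefully to
its members) emits a box whose corners and score are weighted means over
the *contributing* members' weights. Three design points were genuinely
open:

- **Fusion never sees ground truth.** Creating an ensemble box only when
  it overlaps a ground-truth box would leak labels at inference time, so
  grouping is among predictions only; IoU against ground truth appears
  exclusively in evaluation, where the 0.5 threshold decides true
  positives.
- **Weights apply to both coordinates and scores.** The rank weights are
  applied to corner coordinates and to confidence scores alike; the
  weighted-mean score normalized by the contributing weights makes
  unanimous identical predictions fuse to themselves exactly (an identity
  the tests pin down). Normalizing the score by the *full* member weight
  sum instead — penalizing boxes not all members voted for — is available
  as `normalize_score_by_all`, off by default.
- **Fused coordinates are convex combinations**, so they always lie inside
  the contributors' coordinate envelope; this invariant is property-tested.

## Matching, PR curves, average precision

Matching is greedy per image: predictions in order of descending
confidence (ties by input order) are matched to the still-unmatched
ground-truth box of highest IoU, provided IoU ≥ 0.5; ties on IoU go to the
lowest ground-truth index. Greedy best-IoU matching is the documented
choice among the matching disciplines in circulation; each ground-truth
box matches at most once, so `TP + FN = |GT|` always — an invariant
checked on every random instance the suite generates. Unmatched
predictions are FP, unmatched ground-truth boxes FN.

Average precision is the area under the precision *envelope*: sweeping the
ranked predictions accumulates precision `TP/(TP+FP)` and recall
`TP/(TP+FN)`, and for each recall level the envelope takes the maximum
precision at that recall or beyond ("all-points" interpolation). This is
the discrete form of the continuous integral `∫₀¹ P(R) dR`; the coarser
11-point interpolation is not used. The task has a single class
(pneumonia-consistent finding), so mAP equals AP. The implementation is
verified against a brute-force suffix-max envelope oracle on a thousand
random small instances.

Zero ground-truth boxes leave AP undefined (an error, not a silent 0);
appending zero-score false positives below all existing scores leaves AP
unchanged, which the suite spot-checks.

## Confidence intervals

Two 95% binomial intervals for the mAP-as-proportion are implemented: the
exact Clopper-Pearson interval from Beta quantiles (`lower = 0` at
`k = 0`, `upper = 1` at `k = n`), and the normal approximation
`p ± z √(p(1−p)/n)` clipped to `[0, 1]`. `evaluate_detections()` defaults
to Clopper-Pearson. The published intervals this package reconstructs in
`scripts/acceptance.R` are, however, symmetric about their point estimates
with half-widths equal to `1.96 √(p(1−p)/1200)` — i.e. they are normal-
approximation intervals at the 1200-image test-set size, even where
Clopper-Pearson is named as the method. Both methods therefore ship, the
reconstruction uses the normal form at `n = 1200`, and this discrepancy is
stated here rather than hidden. Treating a continuous mAP as a
binomial proportion is itself a reconstruction of reported practice, not a
statistical recommendation; a resampling interval would be the rigorous
alternative and is out of scope.

The standard classification suite (accuracy, sensitivity, precision,
F-score, MCC, kappa) operates on explicit confusion counts. MCC is the
most informative of these under class imbalance because it uses all four
cells; when its denominator vanishes (a degenerate all-one-class
classifier) it is returned as 0 with an explicit `mcc_undefined` flag
rather than `NaN`.

## The synthetic scenario generator

`generate_scenario()` emulates the statistical structure of a
multi-detector CXR test set so fusion and evaluation can be exercised end
to end with no images: per image a uniform 0–2 ground-truth boxes (the
typical count of annotated pneumonia regions), placed uniformly in a
512-px frame with sides uniform in 48–160 px (lesion scale); `K = 3`
detectors that independently re-propose each box with Gaussian corner
jitter (SD 12 px), miss it with probability 0.1, and add Poisson spurious
boxes (0.5 per image); and IoU-correlated confidences
`score = 0.95 − 0.3 (1 − IoU) + N(0, 0.03)`, clipped to `[0, 1]`, so
better-localized proposals rank higher. These defaults were fixed once as
a realistic moderate-noise regime — jitter noticeably below the box scale,
high but imperfect sensitivity, a nonzero but small false-positive load —
and are the regime in which the ensemble-uplift property is asserted.

Conventions worth noting:

- Jitter is applied per corner, independently — the simplest noise model
  that still exercises IoU-threshold grouping; jittered boxes that would
  degenerate are clamped back to a 1-px minimum extent inside the frame.
- Within an image, ground-truth boxes are resampled until pairwise IoU is
  below 0.25: real annotations mark distinct findings, and coincident
  ground-truth boxes would make even an ideal detector unable to reach
  mAP 1 after NMS.
- One global seed drives a per-model stream (`seed + model index`), so
  adding a fourth detector does not perturb the first three — a property
  the tests check byte-for-byte.
- Spurious boxes have no source box; their score takes IoU = 0 in the
  confidence model, landing them well below jittered true proposals on
  average but within filter reach.

What the generator does *not* emulate: real CXR pixel content, reader
variability in the annotations, correlated errors between detectors
sharing a backbone, and confidence miscalibration. Passing the synthetic
end-to-end tests therefore demonstrates the correctness of the fusion and
evaluation machinery under controlled noise — it does not certify
performance on real data, where inter-detector correlation in particular
can shrink the ensemble's advantage.

In the noiseless limit (`jitter_sd = 0`, `detect_prob = 1`,
`fp_rate = 0`) every member reproduces ground truth and the fused mAP is
exactly 1 — the pipeline-identity check. Under the default moderate-noise
regime, averaging three members' independent jitter cancels localization
noise, and the fused mAP meets or beats the best single member in nearly
all seeded replicates; the suite asserts a majority over 50 replicates,
and `scripts/acceptance.R` reports the observed fraction and the mean
uplift over the member average.

## Problem sizes and numerical choices

The shipped tests run the oracle comparison on 1000 random instances of at
most 6 predictions and 4 ground-truth boxes, and the uplift property on 50
replicates of the default 50-image scenario — sizes at which brute-force
oracles are exact and the whole suite completes in well under a minute,
while every code path (empty images, ties, boundary scores) is still
reached. Numerical guards: log arguments clamped at `1e-12`; Tversky
`ε = 1e-7`; score ties broken by input order and IoU ties by lowest
ground-truth index (determinism); box validity enforced at construction so
geometry never divides by a zero union.

## Known limitations

Single-class only (no per-class weighting or multi-class mAP); no
COCO-style mAP@[.5:.95] sweep; no soft-NMS or learned fusion weights; no
AUROC/AUPRC from image-level classifier probabilities (those require the
classifier outputs, not boxes); no DICOM ingestion; the binomial treatment
of mAP is a faithful reconstruction of reported practice rather than an
endorsement.
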