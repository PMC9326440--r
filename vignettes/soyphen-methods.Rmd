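---
title: "Methods: soybean flower/pod phenotyping statistics in soyphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soybean flower/pod phenotyping statistics in soyphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soyphen)
```

## What this package computes

Image-based soybean phenotyping studies photograph every main-stem node of a
plant through the reproductive season, detect flowers and pods in the images,
and turn detection counts into agronomic statistics: flower drop rate, pod
drop rate, pod formation rate, their breakdown across reproductive stages
R1–R8, and spatial distributions over the plant. `soyphen` implements the
quantitative machinery of that workflow — everything around the trained
detectors, which it deliberately does not contain. A detector is an
exchangeable adapter (a function from an image reference to a detection
table), and a seeded synthetic module provides both a perfect oracle adapter
and a noisy one with known error rates, so every downstream statistic can be
validated against a ground truth that field data never offers.

## Annotations, coordinates and splitting

Annotations use the PASCAL VOC XML dialect, whose pixel coordinates are
1-based and inclusive. Internally all boxes are 0-based and half-open, so a
box's area is exactly `(x_max - x_min) * (y_max - y_min)` and two boxes that
merely touch have zero intersection. The conversion happens only in
`parse_voc()` / `write_voc()`; keeping one unambiguous convention internally
avoids the classic off-by-one in IOU arithmetic while staying faithful to the
dialect on disk.

`rescale_annotation()` scales each axis independently (raw captures are
3024×4032; the working resolution is 640×640), which preserves every box's
*relative* area exactly — the quantity the size stratification below depends
on.

`split_dataset()` reproduces the two-stage splitting convention: the
train+validation pool versus test at 8:2, then train versus validation at
9:1. Fractional sizes are resolved by flooring toward the earlier pool
(`n_trainval = floor(0.8 n)`, `n_train = floor(0.9 n_trainval)`), the unique
simple rounding rule that reproduces both published partition rows (1364 /
152 / 379 of 1895 images and 1938 / 216 / 539 of 2693). The shuffle is a
seeded permutation of the lexicographically sorted ids, so identical seeds
give identical member lists regardless of input order.

## Anchor-box optimization

Detector anchor shapes are fitted by k-means over normalized box
width/height pairs under the distance `d(box, centroid) = 1 − IOU(box,
centroid)`, where the IOU overlays the two shapes at a common corner:
`intersection = min(w_a, w_b) · min(h_a, h_b)`. Euclidean distance would
over-weight large boxes; the IOU distance is scale-balanced, which is the
reason this variant displaced plain k-means for anchor selection. How the
two width/height pairs are overlapped is a genuine free choice — co-anchoring
at a corner and centering give identical numbers, so we use the corner
convention standard in anchor clustering.

Implementation choices:

* **Assignment** maximizes IOU (equivalently minimizes the distance);
  iteration stops when the assignment is unchanged between two consecutive
  passes, or at `max_iter`.
* **Update** is the per-dimension **median** of cluster members by default.
  Under a non-Euclidean distance the mean is not the within-cluster
  minimizer, and the median is robust to the long right tail of box sizes;
  the mean is available via `update = "mean"` for comparison.
* **Initialization** is k-means++-style seeding under the same distance,
  with 5 restarts by default; the best restart by mean best-IOU is kept.
  Everything is seeded, so fits are reproducible.
* **Empty clusters** are re-seeded from the box currently farthest from its
  centroid.

`mean_iou_curve()` evaluates the fit across candidate anchor counts; the
anchor count is chosen where the curve flattens (in the source study the
elbow analysis selected k = 18). `derive_aspect_ratios()` then reduces the k
centroid aspect ratios (`h/w`; tall pods have ratios above 1) to a few
representative values by grouping *sorted* ratios into contiguous groups and
returning group means. We compute the optimal contiguous partition exactly by
dynamic programming on prefix sums rather than running a seeded 1-D k-means:
for sorted 1-D data the optimal k-means solution *is* a contiguous partition,
so the DP returns the same optimum deterministically. On the centroid ratios
{0.7, 0.8, 1.7, 1.9, 3.0, 3.4} this yields the published triple
(0.75, 1.8, 3.2).

Size stratification follows the Microsoft COCO criteria on pixel area:
small ≤ 32² = 1024, large ≥ 96² = 9216, medium between. The published
stratum definitions overlap at equality, so a tie-break had to be fixed:
areas of exactly 1024 are small and exactly 9216 are large. Areas are
computed on pre-rescale pixel coordinates.

## Detection evaluation

`match_detections()` implements the PASCAL matching protocol at a fixed IOU
threshold (default 0.5, the threshold used for all reported detection
results): detections are ranked by descending confidence and each greedily
claims the unmatched same-class ground-truth box of highest IOU at or above
the threshold; a detection overlapping only already-claimed boxes is a false
positive. Ties in IOU break toward the earlier ground-truth index and equal
confidences keep input order, so matching is deterministic.

`average_precision()` computes the raw summation
`AP = Σ_k P(k) · ΔR(k)`. The published formula indexes k over test *images*,
which does not yield a well-defined precision–recall walk; the standard
reading — k over ranked detections — is implemented. Raw (uninterpolated)
summation is the default because it is the literal reading of the summation
formula; all-point interpolation (`mode = "interp"`, the monotone precision
envelope) is provided for comparison with tools that report interpolated AP.
The raw walk is verified in the test suite against an independent oracle
that enumerates every confidence threshold and recomputes TP/FP counts from
scratch. `mean_average_precision()` is the unweighted class mean.

Segmentation quality uses `mean_iou_segmentation()`: per-class pixel IoU
`TP/(TP+FP+FN)` from the confusion matrix, averaged over the K+1 classes
including background. A class absent from both masks has an empty union; we
count it as IoU 1 (the masks agree the class is absent) and flag it in the
output, since silently dropping such classes would make MIoU depend on the
label universe.

## Fusion counting and agreement

`run_fusion()` mirrors the serial fusion design: each per-node image passes
through the flower detector, then the pod detector; per-node counts are the
numbers of detections per class at or above a confidence threshold (default
0.5 — the original count threshold is unstated, and 0.5 is the conventional
operating point); node rows are emitted as CSV with one `TOTAL` pseudo-node
row per plant, ordered by (plant, node, date).

Agreement with manual counts is summarized two ways, matching how counting
studies report it: the error distribution (shares of samples with absolute
error 0, ≤ 1, ≤ 2) and a linear fit. `count_agreement()` regresses manual on
predicted counts but reports R² as the squared Pearson correlation, which is
identical to the OLS R² in simple regression and indifferent to the
regression direction the original figures leave ambiguous. Under a detector
that only misses (probability p, no spurious detections), predicted counts
are a binomial thinning of the truth, so the regression of noisy on true
counts has slope `1 − p`; the test suite and acceptance script verify this
parameter recovery within three standard errors.

## Phenology statistics

An event log records `(plant, node, date, event_type)` with event types
`flower_open`, `flower_drop`, `pod_form`, `pod_drop`. In a complete log
every opened flower resolves to exactly one fate: dropped as a flower
(count TNOFD), formed a pod that later dropped (TNOPD), or formed a pod that
survived (TNOPF). The three rates share the denominator
`TNOFD + TNOPD + TNOPF`:

* FDR = 100 · TNOFD / Σ
* PDR = 100 · TNOPD / Σ
* PFR = 100 · TNOPF / Σ

so they sum to exactly 100 before rounding — an identity the tests assert on
arbitrary counts. (The published definition block repeats the label "TNOPD"
for two different quantities; following the numerator of the FDR formula,
flowers dropped is housed as TNOFD.)

Two auxiliary rates cover the arithmetic that published per-sample tables
actually print. `flower_drop_rate(dropped, total)` is the simple
`dropped/total` percentage of the flower table's count columns.
`organ_drop_rate(a, b) = 100·b/(a+b)` is an organ-conditional rate over two
counts: the published pod table's printed rates satisfy exactly this
relation for all six samples, while being mutually inconsistent with the
shared-denominator formula under the printed column labels — whether the
columns are swapped or the rate is genuinely conditional cannot be resolved
from the text, so both computations are provided and neither is asserted as
the intended one.

`stage_breakdown()` attributes each drop to the half-open stage interval
`[Rk, Rk+1)` containing its date (the source writes "R1∼R2" without a
boundary rule; half-open intervals make stage assignment a partition) and
reports each interval's percentage of all drops of that type. Percentages
are reported at full precision; rounded to 2 dp they sum to 100 within 0.05.
Published cells are occasionally truncated rather than rounded, so
table-reproduction tests use a tolerance of 0.01.

`assign_layers()` divides the main stem into contiguous lower/middle/upper
thirds from node 1 upward, giving the remainder nodes to the lower layers
first (soybean plants fill from the bottom); the rule is documented and the
layering is an explicit argument everywhere it is consumed.
`daily_series()` integrates the log into standing counts — a flower leaves
the standing-flower count when it drops *or* becomes a pod — and flags any
date where a count would go negative as a log inconsistency.

## The synthetic-data module

The generators emulate the *structure* of the study's data, not its
appearance:

* `simulate_annotations()` draws box areas log-uniform within a stratum
  chosen from a small/medium/large mixture of (0.50, 0.35, 0.15) — the
  study's area histogram is strongly small-target-heavy — with image-area
  fractions capped at 0.25 (the observed range of the training
  annotations) and aspect ratios scattered lognormally around the published
  triple (0.75, 1.8, 3.2), on 640×640 images.
* `simulate_detections()` misses each true box independently with `p_miss`,
  jitters survivors' coordinates with clipped Gaussian noise, and adds
  Poisson-distributed spurious boxes whose shapes are resampled from the
  true-box population, so false positives are not separable by shape alone.
  True and false positives draw confidences from Beta(5, 1) and Beta(1, 3)
  respectively, making confidence ranking informative without being
  perfect. The hidden provenance of every detection is returned for
  evaluator validation.
* `simulate_phenology()` opens flowers per node per day from a Poisson whose
  intensity depends on the stage (defaults concentrate bloom in R1–R4 and
  yield roughly 250 flowers per 15-node plant over the season, inside the
  98–388 per-plant range of the published samples), assigns each flower a
  fate from a probability vector — default (0.625, 0.205, 0.17), matching an
  overall flower-drop rate near 62% and a conditional pod-drop rate near
  55% — and schedules drop/formation events with Poisson lags (means:
  5 days to flower drop, 7 days to pod formation, 14 more to pod drop),
  clamped to the calendar window so the log is conservation-complete. The
  default calendar spans the 2019 season, 25 June (R1) to 30 September
  (R8), with intermediate boundaries at typical stage spacings.

What passing tests on these generators shows — and does not show: the
statistics are exact bookkeeping, so validating them against generators with
known parameters establishes correctness of the *machinery*; it says nothing
about detector accuracy on real field images, occlusion, disease damage, or
observation gaps, none of which the generators model.

## Numerical choices and problem sizes

Degenerate inputs are errors rather than silent defaults: empty id lists,
duplicate ids, zero fate denominators, constant predictors in the agreement
fit, masks of unequal shape, dates before R1, negative standing counts.
Precision/recall with an empty denominator return 0 with a warning flag, the
one case where a defined value is more useful than an error. All stochastic
behaviour flows through explicit integer seeds.

The packaged checks run at deliberately modest sizes chosen to make their
statistical bounds meaningful while staying fast: ~1000 boxes for the
miss-rate recovery (99% binomial half-width ±4.3 points at p = 0.3), ≥400
flowers for the fate-probability recovery (±6.5 points at p = 0.5), 50
random instances of ≤20 detections for the AP/oracle equivalence, and 100
single-node plants for the slope recovery.

## Limitations

No trained detector ships with the package; the adapter seam is where one
attaches. Pods are not causally linked to the flowers that produced them —
the event bookkeeping is per node, not per organ, so pod tracing remains
out of reach exactly as it does for the field protocol. Branch flowers are
folded into their main-stem node. The dataset split is unstratified (the
original split's stratification, if any, is unstated).
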