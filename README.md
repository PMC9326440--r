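# soyphen

Quantitative machinery for image-based soybean flower and pod phenotyping.

Phenotyping studies of soybean flowering photograph every main-stem node of
a plant through the reproductive season (stages R1–R8), run flower and pod
detectors over the images, and turn the counts into agronomic statistics.
`soyphen` implements everything in that workflow *except* the trained
detector, which enters only as an exchangeable adapter:

* **Annotation handling** — PASCAL VOC XML in/out, rescaling to the working
  resolution, and deterministic train/validation/test splitting with the
  8:2 / 9:1 floor convention.
* **Anchor-box optimization** — k-means over normalized box shapes under the
  distance `d(box, centroid) = 1 − IOU(box, centroid)` (shapes co-anchored
  at a corner, `intersection = min(w_a, w_b)·min(h_a, h_b)`), mean-IOU elbow
  curves, aspect-ratio derivation, and COCO-style small/medium/large
  stratification (thresholds 32² and 96² px).
* **Detection evaluation** — greedy confidence-ranked matching at an IOU
  threshold, precision `TP/(TP+FP)` and recall `TP/(TP+FN)`, raw-summation
  average precision `AP = Σ_k P(k)·ΔR(k)`, class-mean mAP, and segmentation
  MIoU from the pixel confusion matrix.
* **Fusion counting** — serial flower-then-pod detection over per-node
  images, per-node counts aggregated to per-plant totals, and agreement
  with manual counts (error distribution at |err| = 0/≤1/≤2, linear fit,
  R²).
* **Drop-rate phenology** — the three fates of an opened flower over the
  shared denominator TNOFD + TNOPD + TNOPF:

  ```
  FDR = 100 · TNOFD / (TNOFD + TNOPD + TNOPF)
  PDR = 100 · TNOPD / (TNOFD + TNOPD + TNOPF)
  PFR = 100 · TNOPF / (TNOFD + TNOPD + TNOPF)
  ```

  plus per-stage breakdowns over half-open intervals [Rk, Rk+1),
  lower/middle/upper node layering, and daily standing-count series.
* **Synthetic data** — seeded generators for annotation sets with the
  study's box-size structure, detector output with known miss/spurious/
  jitter rates, and conservation-complete flower-fate event logs, so every
  statistic is testable against known parameters.

See `vignettes/soyphen-methods.Rmd` for the full account of the models,
conventions and design choices.

## Worked example

```r
library(soyphen)

# deterministic 8:2 then 9:1 split of 1895 image ids
split_dataset(sprintf("img%04d", 1:1895), seed = 42)
#> <dataset_split> train 1364 / val 152 / test 379 (seed 42)

# synthetic annotations -> anchor shapes under the 1-IOU distance
anns <- simulate_annotations(60, seed = 42, boxes_per_image = 5)
fit <- anchor_kmeans(normalized_wh(anns), k = 6, seed = 42)
fit
#> <anchor_kmeans> k = 6, 304 boxes, mean best-IOU = 0.5677
derive_aspect_ratios(fit, 3)
#> [1] 1.640175 1.729165 1.815019

# score a noisy synthetic detector against the ground truth
dets <- simulate_detections(anns, detection_noise_config(
  p_miss = 0.15, p_spurious_per_image = 0.5, jitter_sd = 2, seed = 42))
rep <- evaluate_detections(anns, dets$detections)
rep$per_class
#>    label tp fp fn precision    recall        ap
#> 1 flower 89 47 56 0.6544118 0.6137931 0.4639486
#> 2    pod 91 61 68 0.5986842 0.5723270 0.3733269

# flower-fate statistics from a simulated two-plant season
events <- simulate_phenology(phenology_sim_config(n_plants = 2, seed = 42))
fc <- tally_fates(events)
fc
#> <fate_counts> flowers dropped 317, pods dropped 121, pods formed 77 (flowers opened 515)
round(fate_rates(fc), 2)
#>   fdr   pdr   pfr
#> 61.55 23.50 14.95
stage_breakdown(events, default_stage_calendar(), "flower_drop")
#> <stage_breakdown> flower_drop: 317 drops of 515 organs (rate 61.55%)
#>  interval   n percent
#>     R1~R2  27   8.52%
#>     R2~R3  78  24.61%
#>     R3~R4 102  32.18%
#>     R4~R5  79  24.92%
#>     R5~R6  26   8.20%
#>     R6~R7   5   1.58%
#>     R7~R8   0   0.00%
```

Here 61.55 / 23.50 / 14.95 are the percentages of opened flowers that
dropped, formed a pod that later dropped, and formed a surviving pod; the
three always sum to 100. The stage table attributes each flower drop to the
reproductive interval containing its date.

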