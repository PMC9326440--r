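# Shared fixture builders: tiny annotations, detection tables and event
# logs constructed in code.

make_boxes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    bounding_box(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]],
                 if (length(r) >= 6) r[[6]] else NA_real_)
  }))
}

# random valid annotation with n boxes inside a w x h image
random_annotation <- function(id, n, w = 640, h = 640) {
  if (n == 0) return(image_annotation(id, w, h))
  x0 <- runif(n, 0, w - 20); y0 <- runif(n, 0, h - 20)
  bw <- runif(n, 5, 20); bh <- runif(n, 5, 20)
  image_annotation(id, w, h, bounding_box(
    round(x0), round(y0), round(x0 + bw), round(y0 + bh),
    sample(c("flower", "pod"), n, replace = TRUE)))
}

det_row <- function(image_id, label, x_min, y_min, x_max, y_max, confidence) {
  data.frame(image_id = image_id, label = label, x_min = x_min,
             y_min = y_min, x_max = x_max, y_max = y_max,
             confidence = confidence, stringsAsFactors = FALSE)
}

# event-log row builder
ev <- function(plant, node, date, type) {
  data.frame(plant_id = plant, node_index = node, date = as.Date(date),
             event_type = type, stringsAsFactors = FALSE)
}

# Independent AP oracle: enumerate every confidence threshold, recompute
# TP/FP counts by thresholding from scratch, and sum precision x
# recall-increment over descending thresholds.  Assumes distinct
# confidences (the instances the tests generate).
ap_threshold_oracle <- function(confidence, is_tp, n_gt) {
  ord <- order(-confidence)
  confidence <- confidence[ord]; is_tp <- is_tp[ord]
  thresholds <- sort(unique(confidence), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (t in thresholds) {
    keep <- confidence >= t
    tp <- sum(is_tp[keep]); fp <- sum(!is_tp[keep])
    p <- tp / (tp + fp)
    r <- tp / n_gt
    ap <- ap + p * (r - r_prev)
    r_prev <- r
  }
  ap
}

# random ranked match instance with distinct confidences
random_match_instance <- function(max_dets = 20) {
  n_det <- sample.int(max_dets, 1)
  is_tp <- runif(n_det) < 0.6
  n_gt <- max(sum(is_tp), 1) + sample(0:3, 1)
  list(n_gt = n_gt, is_tp = is_tp, # is_tp is in rank order
       confidence = sort(sample(seq(0.01, 0.99, by = 0.01), n_det),
                         decreasing = TRUE),
       label = "flower", iou_thresh = 0.5)
}

# Table 6, printed per-sample counts (flowers dropped, total flowers) and
# flower-drop-rate column
table6_counts <- data.frame(
  sample = c("DN252(1)", "DN252(2)", "DN252(3)",
             "HN51(1)", "HN51(2)", "HN51(3)"),
  dropped = c(110, 101, 74, 196, 179, 142),
  total = c(221, 143, 98, 388, 294, 210),
  rate = c(49.77, 70.63, 75.51, 50.52, 60.88, 67.62),
  stringsAsFactors = FALSE
)

# Table 7, printed per-sample count columns and pod-drop-rate column
table7_counts <- data.frame(
  sample = c("HN51(1)", "HN51(2)", "HN51(3)",
             "DN252(1)", "DN252(2)", "DN252(3)"),
  col1 = c(111, 47, 35, 48, 15, 10),
  col2 = c(81, 68, 33, 63, 27, 14),
  rate = c(42.18, 59.13, 48.53, 56.75, 64.28, 58.33),
  stringsAsFactors = FALSE
)
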