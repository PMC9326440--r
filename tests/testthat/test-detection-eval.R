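test_that("positional box IOU matches hand values", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(10, 10, 20, 20)), 0) # corner touch
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3) # 50/150
  expect_equal(box_iou(bounding_box(0, 0, 4, 4, "x"),
                       bounding_box(2, 2, 6, 6, "x")), 4 / 28)
})

test_that("greedy matching follows the PASCAL protocol", {
  gt <- list(image_annotation("i1", 100, 100,
                              bounding_box(10, 10, 30, 30, "flower")))
  # one detection at IOU 0.6+: TP
  d1 <- det_row("i1", "flower", 10, 10, 30, 26, 0.9)
  mr <- match_detections(gt, d1, "flower")
  expect_equal(c(mr$tp, mr$fp, mr$fn), c(1, 0, 0))

  # two overlapping detections on one GT: higher confidence wins, other FP
  d2 <- rbind(det_row("i1", "flower", 10, 10, 30, 30, 0.9),
              det_row("i1", "flower", 11, 11, 31, 31, 0.8))
  mr2 <- match_detections(gt, d2, "flower")
  expect_equal(c(mr2$tp, mr2$fp, mr2$fn), c(1, 1, 0))
  expect_equal(mr2$is_tp, c(TRUE, FALSE)) # descending-confidence order

  # no detections: all GT are FN
  gt3 <- list(image_annotation("i1", 100, 100, make_boxes(
    list(0, 0, 10, 10, "flower"), list(20, 20, 40, 40, "flower"),
    list(50, 50, 70, 70, "flower"))))
  mr3 <- match_detections(gt3, d1[0, ], "flower")
  expect_equal(c(mr3$tp, mr3$fp, mr3$fn), c(0, 0, 3))
  expect_equal(nrow(mr3$unmatched_gt), 3)

  # unknown image id is an error
  expect_error(match_detections(gt, det_row("nope", "flower", 0, 0, 5, 5, 0.5),
                                "flower"), "unknown image_id")
})

test_that("matching conserves counts on random instances", {
  set.seed(31)
  for (i in 1:10) {
    gt <- lapply(1:3, function(j) random_annotation(paste0("im", j), sample(0:5, 1)))
    cfg <- detection_noise_config(p_miss = 0.3, p_spurious_per_image = 1,
                                  jitter_sd = 2, seed = i)
    dets <- simulate_detections(gt, cfg)$detections
    for (lab in c("flower", "pod")) {
      mr <- match_detections(gt, dets, lab)
      n_gt <- sum(vapply(gt, function(a) sum(a$boxes$label == lab), numeric(1)))
      expect_equal(mr$tp + mr$fn, n_gt)
      expect_equal(mr$tp + mr$fp, sum(dets$label == lab))
    }
  }
})

test_that("precision and recall follow the TP/FP/FN arithmetic", {
  expect_equal(unname(precision_recall(list(tp = 8, fp = 2, fn = 2))),
               c(0.8, 0.8), ignore_attr = TRUE)
  expect_equal(unname(precision_recall(list(tp = 5, fp = 0, fn = 0))),
               c(1, 1), ignore_attr = TRUE)
  expect_warning(pr <- precision_recall(list(tp = 0, fp = 5, fn = 0)),
                 "denominator")
  expect_equal(pr[["precision"]], 0)
})

test_that("raw AP reproduces the hand-walked ranked example", {
  # perfect ranking: all GT found first, no FP
  perfect <- list(n_gt = 3L, is_tp = rep(TRUE, 3), confidence = c(.9, .8, .7))
  expect_equal(average_precision(perfect), 1)

  # ranks (TP, FP, TP) over 2 GT: 1*0.5 + 0.5*0 + (2/3)*0.5
  mixed <- list(n_gt = 2L, is_tp = c(TRUE, FALSE, TRUE),
                confidence = c(.9, .8, .7))
  expect_equal(average_precision(mixed), 1 * 0.5 + (2 / 3) * 0.5)
  expect_error(average_precision(list(n_gt = 0L, is_tp = TRUE,
                                      confidence = 1)), "undefined")
})

test_that("raw AP equals the threshold-enumeration oracle on random instances", {
  set.seed(17)
  for (i in 1:50) {
    inst <- random_match_instance(20)
    expect_equal(average_precision(inst),
                 ap_threshold_oracle(inst$confidence, inst$is_tp, inst$n_gt),
                 tolerance = 1e-12)
  }
})

test_that("appending a worst-ranked FP never raises AP; a TP never lowers it", {
  set.seed(19)
  for (i in 1:20) {
    inst <- random_match_instance(15)
    base <- average_precision(inst)
    with_fp <- list(n_gt = inst$n_gt, is_tp = c(inst$is_tp, FALSE),
                    confidence = c(inst$confidence, 0.001))
    with_tp <- list(n_gt = inst$n_gt + 1L, is_tp = c(inst$is_tp, TRUE),
                    confidence = c(inst$confidence, 0.001))
    expect_lte(average_precision(with_fp), base + 1e-12)
    # appending a TP adds recall mass at the tail precision
    expect_gte(average_precision(with_tp) * (1 + 1e-12),
               average_precision(list(n_gt = inst$n_gt + 1L,
                                      is_tp = inst$is_tp,
                                      confidence = inst$confidence)))
    expect_true(all(c(base, average_precision(with_fp)) >= 0))
    expect_true(all(c(base, average_precision(with_fp)) <= 1))
  }
})

test_that("interpolated AP dominates raw AP", {
  set.seed(23)
  for (i in 1:20) {
    inst <- random_match_instance(15)
    expect_gte(average_precision(inst, "interp") + 1e-12,
               average_precision(inst, "raw"))
  }
})

test_that("mAP is the unweighted class mean", {
  expect_equal(mean_average_precision(c(1, 0.5)), 0.75)
  expect_equal(mean_average_precision(0.62), 0.62)
  aps <- c(0.3, 0.8, 0.55)
  expect_equal(mean_average_precision(aps),
               mean_average_precision(rev(aps)))
})

test_that("noise-free synthetic detections evaluate perfectly", {
  anns <- simulate_annotations(8, seed = 101, boxes_per_image = 3)
  dets <- simulate_detections(anns, detection_noise_config(seed = 5))$detections
  rep <- evaluate_detections(anns, dets)
  expect_equal(rep$per_class$precision, rep(1, nrow(rep$per_class)))
  expect_equal(rep$per_class$recall, rep(1, nrow(rep$per_class)))
  expect_equal(rep$map, 1)
})

test_that("segmentation MIoU matches the hand confusion matrix", {
  expect_equal(as.numeric(mean_iou_segmentation(c(0, 1, 1, 0), c(0, 1, 1, 0))), 1)
  # gt = [0,0,1,1], pred = [0,0,0,0]: class0 IoU 0.5, class1 IoU 0
  m <- mean_iou_segmentation(c(0, 0, 0, 0), c(0, 0, 1, 1))
  expect_equal(as.numeric(m), 0.25)
  expect_equal(attr(m, "per_class"), c(0.5, 0))
  # symmetry in FP/FN
  set.seed(29)
  a <- matrix(sample(0:2, 64, replace = TRUE), 8)
  b <- matrix(sample(0:2, 64, replace = TRUE), 8)
  expect_equal(as.numeric(mean_iou_segmentation(a, b)),
               as.numeric(mean_iou_segmentation(b, a)))
  # absent-from-both classes count as IoU 1 and are flagged
  m2 <- mean_iou_segmentation(c(0, 0), c(0, 0), n_classes = 2)
  expect_equal(as.numeric(m2), 1)
  expect_equal(attr(m2, "empty_classes"), 1L)
  expect_error(mean_iou_segmentation(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape")
})
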