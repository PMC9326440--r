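# Detection scoring: positional IOU, greedy confidence-ranked matching,
# precision/recall, average precision (raw summation and interpolated),
# mAP, and segmentation mean-IoU.

#' Positional IOU of two boxes
#'
#' Intersection-over-union of axis-aligned boxes at their actual positions
#' (half-open convention, so boxes that only touch have IOU 0).
#'
#' @param a,b boxes: numeric vectors `(x_min, y_min, x_max, y_max)` or
#'   one-row box tables.
#' @return IOU in `[0, 1]`; 0 for disjoint boxes.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)) # 1/3
#' @export
box_iou <- function(a, b) {
  a <- as_box_vec(a); b <- as_box_vec(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
             inter)
}

as_box_vec <- function(x) {
  if (is.data.frame(x)) {
    as.numeric(x[1, c("x_min", "y_min", "x_max", "y_max")])
  } else as.numeric(x[1:4])
}

validate_detections <- function(dets) {
  need <- c("image_id", "label", "x_min", "y_min", "x_max", "y_max",
            "confidence")
  missing <- setdiff(need, names(dets))
  if (length(missing)) {
    stop("detection table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(dets) && any(is.na(dets$confidence))) {
    stop("detections must carry a confidence")
  }
  if (nrow(dets) && any(dets$confidence < 0 | dets$confidence > 1)) {
    stop("confidence outside [0, 1]")
  }
  invisible(dets)
}

#' Greedy matching of detections to ground truth
#'
#' Matches detections of one class to ground-truth boxes per the PASCAL
#' protocol: detections are walked in descending confidence and each is
#' greedily matched to the not-yet-matched ground-truth box of the same
#' class in the same image with the highest IOU at or above `iou_thresh`
#' (a true positive); detections without such a box — including those whose
#' best overlap is an already-matched box — are false positives.  Leftover
#' ground-truth boxes are false negatives.  Ties in IOU break toward the
#' earlier ground-truth index; equal confidences keep input order.
#'
#' @param gt list of [image_annotation()] objects (ground truth).
#' @param dets detection table: columns `image_id`, `label`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, `confidence`.
#' @param label class to evaluate, e.g. `"flower"`.
#' @param iou_thresh IOU threshold, default 0.5.
#' @return an object of class `match_result`: counts `tp`, `fp`, `fn`,
#'   `n_gt`, the logical vector `is_tp` over detections in
#'   descending-confidence order, their `confidence`, and
#'   `unmatched_gt` (data frame of image_id/index pairs).
#' @export
match_detections <- function(gt, dets, label, iou_thresh = 0.5) {
  stopifnot(is.list(gt), length(gt) >= 1)
  validate_detections(dets)
  gt_ids <- vapply(gt, function(a) a$image_id, character(1))
  if (anyDuplicated(gt_ids)) stop("duplicate image_id in ground truth")
  names(gt) <- gt_ids

  dets <- dets[dets$label == label, , drop = FALSE]
  if (nrow(dets) && !all(dets$image_id %in% gt_ids)) {
    bad <- setdiff(unique(dets$image_id), gt_ids)
    stop("detection references unknown image_id: ", paste(bad, collapse = ", "))
  }
  # stable sort: equal confidences keep input order
  dets <- dets[order(-dets$confidence), , drop = FALSE]

  gt_boxes <- lapply(gt, function(a) {
    b <- a$boxes
    b[b$label == label, , drop = FALSE]
  })
  n_gt <- sum(vapply(gt_boxes, nrow, integer(1)))
  matched <- lapply(gt_boxes, function(b) rep(FALSE, nrow(b)))

  is_tp <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    img <- dets$image_id[i]
    b <- gt_boxes[[img]]
    if (!nrow(b)) next
    ious <- vapply(seq_len(nrow(b)), function(j) {
      box_iou(dets[i, ], b[j, ])
    }, numeric(1))
    ious[matched[[img]]] <- -1 # already claimed
    j <- which.max(ious)       # ties break to the earlier index
    if (ious[j] >= iou_thresh) {
      is_tp[i] <- TRUE
      matched[[img]][j] <- TRUE
    }
  }
  unmatched <- do.call(rbind, lapply(names(matched), function(img) {
    idx <- which(!matched[[img]])
    if (!length(idx)) return(NULL)
    data.frame(image_id = img, gt_index = idx, stringsAsFactors = FALSE)
  }))
  if (is.null(unmatched)) {
    unmatched <- data.frame(image_id = character(), gt_index = integer(),
                            stringsAsFactors = FALSE)
  }
  structure(
    list(label = label, tp = sum(is_tp), fp = sum(!is_tp),
         fn = n_gt - sum(is_tp), n_gt = n_gt, is_tp = is_tp,
         confidence = dets$confidence, iou_thresh = iou_thresh,
         unmatched_gt = unmatched),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> class '%s' @ IOU %.2f: TP %d, FP %d, FN %d\n",
              x$label, x$iou_thresh, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision and recall of a match result
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`.  Empty
#' denominators yield 0 with attribute `"degenerate" = TRUE` and a warning.
#'
#' @param mr a [match_detections()] result, or a list with `tp`, `fp`, `fn`.
#' @return named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(mr) {
  degenerate <- FALSE
  p <- if (mr$tp + mr$fp > 0) mr$tp / (mr$tp + mr$fp) else {
    degenerate <- TRUE; 0
  }
  r <- if (mr$tp + mr$fn > 0) mr$tp / (mr$tp + mr$fn) else {
    degenerate <- TRUE; 0
  }
  if (degenerate) warning("empty denominator; precision/recall set to 0")
  out <- c(precision = p, recall = r)
  attr(out, "degenerate") <- degenerate
  out
}

#' Average precision from a ranked match result
#'
#' Walks the detections in descending confidence, accumulating
#' `precision(k)` and `recall(k)` at each rank, and returns the raw
#' summation `sum_k precision(k) * (recall(k) - recall(k-1))`.  Mode
#' `"interp"` instead applies all-point interpolation (the monotone
#' precision envelope) before summing, for comparability with tools that
#' report interpolated AP.
#'
#' @param mr a [match_detections()] result with at least one ground-truth
#'   box of the class.
#' @param mode `"raw"` (default) or `"interp"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(mr, mode = c("raw", "interp")) {
  mode <- match.arg(mode)
  if (mr$n_gt < 1) stop("average precision undefined without ground truth")
  if (!length(mr$is_tp)) return(0)
  tp_cum <- cumsum(mr$is_tp)
  fp_cum <- cumsum(!mr$is_tp)
  precision <- tp_cum / (tp_cum + fp_cum)
  recall <- tp_cum / mr$n_gt
  if (mode == "interp") {
    precision <- rev(cummax(rev(precision)))
  }
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' Mean average precision over classes
#'
#' Unweighted mean of per-class APs.
#'
#' @param aps numeric vector of per-class AP values.
#' @return mAP in `[0, 1]`.
#' @export
mean_average_precision <- function(aps) {
  stopifnot(length(aps) >= 1)
  mean(as.numeric(aps))
}

#' Full detection evaluation report
#'
#' Convenience wrapper: runs [match_detections()] and [average_precision()]
#' for every class present in the ground truth and assembles the per-class
#' table plus mAP.
#'
#' @inheritParams match_detections
#' @param mode AP mode, `"raw"` or `"interp"`.
#' @return a list with `per_class` (data frame: label, tp, fp, fn,
#'   precision, recall, ap) and `map`.
#' @export
evaluate_detections <- function(gt, dets, iou_thresh = 0.5, mode = "raw") {
  labels <- sort(unique(unlist(lapply(gt, function(a) a$boxes$label))))
  if (!length(labels)) stop("no ground-truth boxes to evaluate against")
  rows <- lapply(labels, function(lab) {
    mr <- match_detections(gt, dets, lab, iou_thresh)
    pr <- suppressWarnings(precision_recall(mr))
    data.frame(label = lab, tp = mr$tp, fp = mr$fp, fn = mr$fn,
               precision = pr[["precision"]], recall = pr[["recall"]],
               ap = average_precision(mr, mode), stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class, map = mean_average_precision(per_class$ap))
}

#' Segmentation mean intersection-over-union
#'
#' Mean over the `K + 1` classes (background is class 0) of the per-class
#' pixel IoU `TP_i / (TP_i + FP_i + FN_i)` computed from the confusion
#' matrix of two equally-shaped integer label grids.  A class absent from
#' both masks has zero union; such classes count as IoU 1 (both masks agree
#' it is absent) and are reported in the attribute `"empty_classes"`.
#'
#' @param pred,gt integer matrices (or vectors) of equal shape with labels
#'   in `0..K`.
#' @param n_classes `K + 1`, the number of classes including background;
#'   defaults to `max(pred, gt) + 1`.
#' @return MIoU in `[0, 1]`, with attributes `"per_class"` and
#'   `"empty_classes"`.
#' @export
mean_iou_segmentation <- function(pred, gt, n_classes = NULL) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt)) {
    stop("prediction and ground-truth masks must have identical shape")
  }
  pred <- as.integer(pred); gt <- as.integer(gt)
  if (any(pred < 0) || any(gt < 0)) stop("labels must be non-negative")
  if (is.null(n_classes)) n_classes <- max(pred, gt) + 1L
  if (any(pred >= n_classes) || any(gt >= n_classes)) {
    stop("labels exceed n_classes - 1")
  }
  iou <- numeric(n_classes)
  empty <- logical(n_classes)
  for (i in seq_len(n_classes) - 1L) {
    tp <- sum(pred == i & gt == i)
    fp <- sum(pred == i & gt != i)
    fn <- sum(pred != i & gt == i)
    if (tp + fp + fn == 0) {
      iou[i + 1] <- 1
      empty[i + 1] <- TRUE
    } else {
      iou[i + 1] <- tp / (tp + fp + fn)
    }
  }
  out <- mean(iou)
  attr(out, "per_class") <- iou
  attr(out, "empty_classes") <- which(empty) - 1L
  out
}
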