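# Anchor-box optimization: k-means under the 1-IOU distance, mean-IOU elbow
# curve, aspect-ratio derivation, and COCO-style size stratification.

#' Aligned IOU between width/height pairs
#'
#' Intersection-over-union of two box shapes co-anchored at a common corner,
#' the standard convention for anchor clustering: the overlap of shapes
#' `(w_a, h_a)` and `(w_b, h_b)` is `min(w_a, w_b) * min(h_a, h_b)`.  The
#' clustering distance is `1 - iou_aligned(a, b)`.  Co-anchoring at a corner
#' and centering give identical values.
#'
#' @param w_a,h_a,w_b,h_b positive box dimensions (vectors recycled; usually
#'   normalized to image size, but any common unit works).
#' @return IOU values in `(0, 1]`.
#' @examples
#' iou_aligned(0.2, 0.2, 0.1, 0.1) # 0.25
#' @export
iou_aligned <- function(w_a, h_a, w_b, h_b) {
  if (any(w_a <= 0) || any(h_a <= 0) || any(w_b <= 0) || any(h_b <= 0)) {
    stop("box dimensions must be positive")
  }
  inter <- pmin(w_a, w_b) * pmin(h_a, h_b)
  inter / (w_a * h_a + w_b * h_b - inter)
}

# n x k matrix of IOUs between every box (rows of wh) and every centroid.
iou_to_centroids <- function(wh, centroids) {
  n <- nrow(wh); k <- nrow(centroids)
  m <- matrix(0, n, k)
  for (j in seq_len(k)) {
    m[, j] <- iou_aligned(wh[, 1], wh[, 2], centroids[j, 1], centroids[j, 2])
  }
  m
}

# k-means++-style seeding under the 1-IOU distance.
seed_centroids <- function(wh, k) {
  n <- nrow(wh)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d <- 1 - iou_aligned(wh[, 1], wh[, 2], wh[idx[1], 1], wh[idx[1], 2])
    for (j in 2:k) {
      w <- d^2
      idx[j] <- if (sum(w) > 0) sample.int(n, 1, prob = w) else sample.int(n, 1)
      d_new <- 1 - iou_aligned(wh[, 1], wh[, 2], wh[idx[j], 1], wh[idx[j], 2])
      d <- pmin(d, d_new)
    }
  }
  wh[idx, , drop = FALSE]
}

lloyd_iou <- function(wh, k, max_iter, update) {
  centroids <- seed_centroids(wh, k)
  assign_prev <- rep(-1L, nrow(wh))
  for (iter in seq_len(max_iter)) {
    ious <- iou_to_centroids(wh, centroids)
    assignment <- max.col(ious, ties.method = "first")
    # empty cluster: re-seed from the box farthest from its centroid
    for (j in which(tabulate(assignment, k) == 0)) {
      best <- ious[cbind(seq_len(nrow(wh)), assignment)]
      far <- which.min(best)
      centroids[j, ] <- wh[far, ]
      assignment[far] <- j
      ious <- iou_to_centroids(wh, centroids)
      assignment <- max.col(ious, ties.method = "first")
    }
    if (identical(assignment, assign_prev)) break
    assign_prev <- assignment
    for (j in seq_len(k)) {
      members <- wh[assignment == j, , drop = FALSE]
      centroids[j, ] <- apply(members, 2, update)
    }
  }
  ious <- iou_to_centroids(wh, centroids)
  assignment <- max.col(ious, ties.method = "first")
  best_iou <- ious[cbind(seq_len(nrow(wh)), assignment)]
  list(centroids = centroids, assignment = assignment,
       mean_iou = mean(best_iou), iterations = iter)
}

#' Anchor-box k-means under the 1-IOU distance
#'
#' Clusters normalized box shapes (width/height pairs) by Lloyd iteration
#' where the distance between a box and a centroid is `1 - IOU` of the
#' co-anchored shapes: the assignment step picks the centroid of maximum
#' IOU, the update step recomputes each centroid from its members, and
#' iteration stops when the assignment no longer changes between two
#' consecutive passes (or at `max_iter`).  Initialization is
#' k-means++-style seeding under the same distance; the best of `restarts`
#' seeded runs by mean best-IOU is returned.
#'
#' The centroid update is the per-dimension `"median"` by default (robust
#' under the non-Euclidean distance); `"mean"` is available.
#'
#' @param wh a two-column matrix or data frame of box widths and heights,
#'   each in `(0, 1]` when normalized (any positive unit is accepted).
#' @param k number of anchors, `1 <= k <=` number of distinct shapes.
#' @param seed integer RNG seed.
#' @param max_iter iteration cap per restart.
#' @param restarts number of seeded initializations.
#' @param update `"median"` or `"mean"` centroid update.
#' @return an object of class `anchor_kmeans` with elements `centroids`
#'   (k x 2 matrix, columns `w`, `h`), `assignment`, `mean_iou`, `k`,
#'   `update`, `seed` and `wh`.
#' @examples
#' set.seed(1)
#' wh <- cbind(w = runif(40, 0.05, 0.3), h = runif(40, 0.05, 0.3))
#' fit <- anchor_kmeans(wh, k = 3, seed = 7)
#' fit$mean_iou
#' @export
anchor_kmeans <- function(wh, k, seed = 1L, max_iter = 100L, restarts = 5L,
                          update = c("median", "mean")) {
  update <- match.arg(update)
  wh <- as.matrix(wh)
  stopifnot(ncol(wh) == 2)
  if (any(wh <= 0)) stop("box dimensions must be positive")
  n_distinct <- nrow(unique(wh))
  if (k < 1) stop("k must be >= 1")
  if (k > n_distinct) {
    stop("k (", k, ") exceeds the number of distinct box shapes (",
         n_distinct, ")")
  }
  update_fun <- if (update == "median") stats::median else mean
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      run <- lloyd_iou(wh, k, max_iter, update_fun)
      if (is.null(best) || run$mean_iou > best$mean_iou) best <- run
    }
  })
  colnames(best$centroids) <- c("w", "h")
  structure(
    list(centroids = best$centroids, assignment = best$assignment,
         mean_iou = best$mean_iou, k = as.integer(k), update = update,
         seed = as.integer(seed), wh = wh),
    class = "anchor_kmeans"
  )
}

#' @export
print.anchor_kmeans <- function(x, ...) {
  cat(sprintf("<anchor_kmeans> k = %d, %d boxes, mean best-IOU = %.4f\n",
              x$k, nrow(x$wh), x$mean_iou))
  cat("Centroids (w, h):\n")
  print(round(x$centroids[order(x$centroids[, "w"] * x$centroids[, "h"]), ,
                          drop = FALSE], 4))
  invisible(x)
}

#' @export
summary.anchor_kmeans <- function(object, ...) {
  sizes <- tabulate(object$assignment, object$k)
  ratios <- object$centroids[, "h"] / object$centroids[, "w"]
  out <- data.frame(
    anchor = seq_len(object$k),
    w = object$centroids[, "w"], h = object$centroids[, "h"],
    aspect_ratio = ratios, n_members = sizes,
    row.names = NULL
  )
  out <- out[order(out$w * out$h), ]
  structure(list(table = out, mean_iou = object$mean_iou, k = object$k),
            class = "summary.anchor_kmeans")
}

#' @export
print.summary.anchor_kmeans <- function(x, ...) {
  cat(sprintf("Anchor k-means fit: k = %d, mean best-IOU = %.4f\n\n",
              x$k, x$mean_iou))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.anchor_kmeans <- function(object, ...) object$centroids

#' Assign new box shapes to fitted anchors
#'
#' @param object an [anchor_kmeans()] fit.
#' @param newdata two-column matrix/data frame of widths and heights; the
#'   training boxes when omitted.
#' @param ... unused.
#' @return integer centroid indices, one per row of `newdata`, with the best
#'   IOU per box as attribute `"iou"`.
#' @export
predict.anchor_kmeans <- function(object, newdata = NULL, ...) {
  wh <- if (is.null(newdata)) object$wh else as.matrix(newdata)
  stopifnot(ncol(wh) == 2)
  ious <- iou_to_centroids(wh, object$centroids)
  assignment <- max.col(ious, ties.method = "first")
  attr(assignment, "iou") <- ious[cbind(seq_len(nrow(wh)), assignment)]
  assignment
}

#' @export
plot.anchor_kmeans <- function(x, ...) {
  plot(x$wh[, 1], x$wh[, 2], col = x$assignment, pch = 16, cex = 0.6,
       xlab = "box width", ylab = "box height",
       main = sprintf("Anchor k-means (k = %d, mean IOU %.3f)",
                      x$k, x$mean_iou), ...)
  graphics::points(x$centroids[, 1], x$centroids[, 2], pch = 4, cex = 2,
                   lwd = 2)
  invisible(x)
}

#' Mean-IOU elbow curve over candidate anchor counts
#'
#' Runs [anchor_kmeans()] for each candidate `k` and records the mean
#' best-IOU, the curve used to pick the anchor count where gains flatten
#' (the published choice was k = 18, where the curve changes slowly over
#' 14-18).
#'
#' @inheritParams anchor_kmeans
#' @param k_values ascending integer vector of candidate anchor counts.
#' @return a `data.frame` with columns `k` and `mean_iou`.
#' @export
mean_iou_curve <- function(wh, k_values, seed = 1L, restarts = 5L,
                           max_iter = 100L, update = "median") {
  stopifnot(length(k_values) >= 1, !is.unsorted(k_values))
  res <- vapply(seq_along(k_values), function(i) {
    anchor_kmeans(wh, k_values[i], seed = seed + i - 1L,
                  max_iter = max_iter, restarts = restarts,
                  update = update)$mean_iou
  }, numeric(1))
  data.frame(k = as.integer(k_values), mean_iou = res)
}

# Exact least-squares partition of sorted 1-D values into g contiguous
# groups (dynamic programme over prefix sums) — the global optimum that
# seeded 1-D k-means approximates.
contiguous_groups_1d <- function(x, g) {
  n <- length(x)
  x <- sort(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) { # cost of group x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, g, n)
  back <- matrix(0L, g, n)
  for (j in seq_len(n)) cost[1, j] <- sse(1, j)
  if (g > 1) {
    for (m in 2:g) {
      for (j in m:n) {
        for (i in m:j) {
          c_ <- cost[m - 1, i - 1] + sse(i, j)
          if (c_ < cost[m, j]) { cost[m, j] <- c_; back[m, j] <- i }
        }
      }
    }
  }
  # recover group boundaries
  groups <- integer(n)
  j <- n
  for (m in g:1) {
    i <- if (m == 1) 1L else back[m, j]
    groups[i:j] <- m
    j <- i - 1L
  }
  split(x, groups)
}

#' Derive grouped aspect ratios from an anchor fit
#'
#' Computes each centroid's aspect ratio `h / w` (tall pods have ratio > 1),
#' partitions the sorted ratios into `n_groups` contiguous groups by an
#' exact least-squares 1-D clustering, and returns the group means in
#' ascending order — the procedure that reduces a fitted anchor set to a
#' small ratio triple such as the published (0.75, 1.8, 3.2).
#'
#' @param model an [anchor_kmeans()] fit, or a numeric vector of ratios.
#' @param n_groups number of ratio groups, at most the number of centroids.
#' @return sorted numeric vector of `n_groups` group-mean ratios.
#' @examples
#' derive_aspect_ratios(c(0.7, 0.8, 1.7, 1.9, 3.0, 3.4), 3) # 0.75 1.80 3.20
#' @export
derive_aspect_ratios <- function(model, n_groups = 3L) {
  ratios <- if (inherits(model, "anchor_kmeans")) {
    model$centroids[, "h"] / model$centroids[, "w"]
  } else as.numeric(model)
  if (n_groups > length(ratios)) {
    stop("n_groups (", n_groups, ") exceeds the number of centroids (",
         length(ratios), ")")
  }
  unname(sort(vapply(contiguous_groups_1d(ratios, n_groups), mean,
                     numeric(1))))
}

#' COCO-style size stratification of a box
#'
#' Classifies boxes by pixel area with the Microsoft COCO thresholds:
#' `area <= 32^2 = 1024` is `small`, `area >= 96^2 = 9216` is `large`,
#' anything between is `medium`.  The published stratum definitions overlap
#' at equality; ties at 1024 go to `small` and at 9216 to `large`.
#'
#' @param boxes a box table (see [bounding_box()]) in pixel units, or a
#'   numeric vector of areas.
#' @return factor with levels `small`, `medium`, `large`.
#' @examples
#' classify_size(c(1024, 5000, 9216)) # small medium large
#' @export
classify_size <- function(boxes) {
  area <- if (is.data.frame(boxes)) {
    validate_boxes(boxes)
    (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
  } else as.numeric(boxes)
  cls <- ifelse(area <= 1024, "small", ifelse(area >= 9216, "large", "medium"))
  factor(cls, levels = c("small", "medium", "large"))
}

#' Image-area fraction of boxes
#'
#' Fraction of the image area occupied by each box; in the study's training
#' annotations these fractions lie in (0, 0.25].
#'
#' @param ann an [image_annotation()], or a box table if `width`/`height`
#'   are supplied.
#' @param width,height image dimensions when `ann` is a bare box table.
#' @return numeric vector of fractions in `(0, 1]`.
#' @export
area_fraction <- function(ann, width = NULL, height = NULL) {
  if (inherits(ann, "image_annotation")) {
    b <- ann$boxes; width <- ann$width; height <- ann$height
  } else {
    b <- ann
    stopifnot(!is.null(width), !is.null(height))
  }
  (b$x_max - b$x_min) * (b$y_max - b$y_min) / (width * height)
}

#' Normalized width/height pairs from annotations
#'
#' Convenience extractor: stacks every box of a list of annotations into the
#' two-column normalized matrix consumed by [anchor_kmeans()].
#'
#' @param anns list of [image_annotation()] objects.
#' @param labels optional subset of labels to keep.
#' @return matrix with columns `w`, `h`, each value in `(0, 1]`.
#' @export
normalized_wh <- function(anns, labels = NULL) {
  rows <- lapply(anns, function(a) {
    b <- a$boxes
    if (!is.null(labels)) b <- b[b$label %in% labels, , drop = FALSE]
    if (!nrow(b)) return(NULL)
    cbind(w = (b$x_max - b$x_min) / a$width,
          h = (b$y_max - b$y_min) / a$height)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(numeric(), 0, 2,
                                  dimnames = list(NULL, c("w", "h")))
  out
}
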