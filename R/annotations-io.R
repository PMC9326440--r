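# PASCAL VOC annotation I/O, rescaling and dataset splitting.
#
# Internal coordinate convention: 0-based, half-open pixel rectangles, so a
# box covering the first 10x10 pixel block is (0, 0, 10, 10) and its area is
# exactly (x_max - x_min) * (y_max - y_min).  VOC XML on disk is 1-based
# inclusive; the conversion happens only in parse_voc()/write_voc().

#' Construct a bounding-box table
#'
#' Builds the validated data frame of axis-aligned boxes used throughout the
#' package.  Coordinates follow the internal 0-based half-open convention:
#' `x_min < x_max`, `y_min < y_max`, and the pixel area is
#' `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param x_min,y_min,x_max,y_max numeric pixel coordinates (vectors recycled
#'   to common length).
#' @param label character category names, e.g. `"flower"` or `"pod"`.
#' @param confidence optional detection confidences in `[0, 1]`; `NA` for
#'   ground-truth boxes.
#' @return a `data.frame` with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `label`, `confidence`.
#' @examples
#' bounding_box(0, 0, 32, 32, "pod")
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max, label,
                         confidence = NA_real_) {
  n <- max(length(x_min), length(y_min), length(x_max), length(y_max),
           length(label))
  if (length(confidence) == 1 && n != 1) confidence <- rep(confidence, n)
  df <- data.frame(
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    label = as.character(label), confidence = as.numeric(confidence),
    stringsAsFactors = FALSE
  )
  validate_boxes(df)
  df
}

validate_boxes <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("x_min", "y_min", "x_max", "y_max", "label")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("box table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$x_min >= df$x_max) || any(df$y_min >= df$y_max)) {
    stop("degenerate box: need x_min < x_max and y_min < y_max")
  }
  if (any(is.na(df$label) | !nzchar(df$label))) {
    stop("box with missing or empty label")
  }
  conf <- df$confidence
  if (!is.null(conf) && any(!is.na(conf) & (conf < 0 | conf > 1))) {
    stop("confidence outside [0, 1]")
  }
  invisible(df)
}

#' Construct an image annotation
#'
#' One annotation is one image: an id, pixel dimensions, and an ordered table
#' of ground-truth boxes (see [bounding_box()]).  Every box must lie within
#' `[0, width] x [0, height]`.
#'
#' @param image_id character image identifier.
#' @param width,height image dimensions in pixels, positive.
#' @param boxes a box table as returned by [bounding_box()]; may have zero
#'   rows.
#' @return an object of class `image_annotation`.
#' @export
image_annotation <- function(image_id, width, height,
                             boxes = bounding_box(numeric(), numeric(),
                                                  numeric(), numeric(),
                                                  character())) {
  stopifnot(length(image_id) == 1, nzchar(image_id))
  width <- as.numeric(width); height <- as.numeric(height)
  if (width <= 0 || height <= 0) stop("image dimensions must be positive")
  validate_boxes(boxes)
  if (nrow(boxes) &&
      (any(boxes$x_min < 0) || any(boxes$y_min < 0) ||
       any(boxes$x_max > width) || any(boxes$y_max > height))) {
    stop("box outside image bounds for image ", image_id)
  }
  structure(
    list(image_id = as.character(image_id), width = width, height = height,
         boxes = boxes),
    class = "image_annotation"
  )
}

#' @export
print.image_annotation <- function(x, ...) {
  cat(sprintf("<image_annotation> %s  %gx%g px, %d box(es)\n",
              x$image_id, x$width, x$height, nrow(x$boxes)))
  if (nrow(x$boxes)) print(utils::head(x$boxes, 10))
  invisible(x)
}

voc_num <- function(node, xpath, what) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) stop("VOC parse error: missing <", what, ">")
  v <- suppressWarnings(as.numeric(xml2::xml_text(n)))
  if (is.na(v)) stop("VOC parse error: non-numeric <", what, ">")
  v
}

#' Parse a PASCAL VOC annotation
#'
#' Reads one VOC XML document (text or file path) into an
#' [image_annotation()].  VOC stores 1-based inclusive pixel coordinates;
#' they are converted to the internal 0-based half-open convention
#' (`x_min = xmin_voc - 1`, `x_max = xmax_voc`, same for y), so a VOC box
#' `(1, 1, 10, 10)` becomes `(0, 0, 10, 10)`.
#'
#' @param xml_text a single string: XML content or a path to an XML file.
#' @return an `image_annotation`.
#' @seealso [write_voc()] for the inverse.
#' @export
parse_voc <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  size <- xml2::xml_find_first(doc, ".//size")
  if (inherits(size, "xml_missing")) {
    stop("VOC parse error: missing <size> block")
  }
  width <- voc_num(size, "./width", "width")
  height <- voc_num(size, "./height", "height")
  fn <- xml2::xml_find_first(doc, "./filename")
  image_id <- if (inherits(fn, "xml_missing")) "unknown" else
    sub("\\.(jpg|jpeg|png|xml)$", "", xml2::xml_text(fn), ignore.case = TRUE)

  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs)) {
    rows <- lapply(objs, function(o) {
      lab_node <- xml2::xml_find_first(o, "./name")
      lab <- if (inherits(lab_node, "xml_missing")) "" else
        xml2::xml_text(lab_node)
      if (!nzchar(lab)) stop("VOC parse error: <object> with empty <name>")
      bb <- xml2::xml_find_first(o, "./bndbox")
      if (inherits(bb, "xml_missing")) {
        stop("VOC parse error: <object> '", lab, "' lacks <bndbox>")
      }
      xmin <- voc_num(bb, "./xmin", "xmin"); ymin <- voc_num(bb, "./ymin", "ymin")
      xmax <- voc_num(bb, "./xmax", "xmax"); ymax <- voc_num(bb, "./ymax", "ymax")
      if (xmin > xmax || ymin > ymax) {
        stop("VOC parse error: inverted <bndbox> in object '", lab, "'")
      }
      data.frame(x_min = xmin - 1, y_min = ymin - 1, x_max = xmax,
                 y_max = ymax, label = lab, confidence = NA_real_,
                 stringsAsFactors = FALSE)
    })
    boxes <- do.call(rbind, rows)
  } else {
    boxes <- bounding_box(numeric(), numeric(), numeric(), numeric(),
                          character())
  }
  image_annotation(image_id, width, height, boxes)
}

#' Serialize an annotation to PASCAL VOC XML
#'
#' Inverse of [parse_voc()] up to whitespace: internal 0-based half-open
#' coordinates are written back as VOC 1-based inclusive integers.
#'
#' @param ann an [image_annotation()].
#' @param path optional file path; when given the XML is written there.
#' @return the XML text, invisibly when `path` is given.
#' @export
write_voc <- function(ann, path = NULL) {
  stopifnot(inherits(ann, "image_annotation"))
  b <- ann$boxes
  if (nrow(b) && (any(b$x_min < 0) || any(b$y_min < 0) ||
                  any(b$x_max > ann$width) || any(b$y_max > ann$height))) {
    stop("refusing to serialize: box outside image bounds")
  }
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(ann$image_id, ".jpg"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(ann$width))
  xml2::xml_add_child(size, "height", format(ann$height))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(b))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$label[i])
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(b$x_min[i] + 1))
    xml2::xml_add_child(bb, "ymin", format(b$y_min[i] + 1))
    xml2::xml_add_child(bb, "xmax", format(b$x_max[i]))
    xml2::xml_add_child(bb, "ymax", format(b$y_max[i]))
  }
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Rescale an annotation to a target resolution
#'
#' Scales every box by `(target_w / width, target_h / height)` independently
#' per axis and sets the image dimensions to the targets, mirroring the
#' reduction of raw captures (e.g. 3024x4032) to the working 640x640
#' resolution.  Relative box areas are preserved exactly.
#'
#' @param ann an [image_annotation()].
#' @param target_w,target_h target dimensions in pixels, positive.
#' @return the rescaled `image_annotation`.
#' @export
rescale_annotation <- function(ann, target_w = 640, target_h = 640) {
  stopifnot(inherits(ann, "image_annotation"), target_w > 0, target_h > 0)
  sx <- target_w / ann$width
  sy <- target_h / ann$height
  b <- ann$boxes
  b$x_min <- b$x_min * sx; b$x_max <- b$x_max * sx
  b$y_min <- b$y_min * sy; b$y_max <- b$y_max * sy
  image_annotation(ann$image_id, target_w, target_h, b)
}

#' Deterministic train/validation/test split
#'
#' Splits image ids by the two-stage ratio used for the flower and pod
#' datasets: train+validation vs test at `1 - test_frac` : `test_frac`
#' (default 8:2), then train vs validation at
#' `1 - val_frac_of_trainval` : `val_frac_of_trainval` (default 9:1).
#' Sizes use the floor convention `n_trainval = floor(n * 0.8)`,
#' `n_test = n - n_trainval`, `n_train = floor(n_trainval * 0.9)`,
#' `n_val = n_trainval - n_train`, which reproduces the published flower
#' (1364/152/379 of 1895) and pod (1938/216/539 of 2693) partitions.
#'
#' Ids are sorted lexicographically and then shuffled by a seeded RNG, so the
#' member lists (not just the sizes) are reproducible.
#'
#' @param ids character vector of unique image ids.
#' @param seed integer RNG seed.
#' @param test_frac fraction of all ids held out as the test set.
#' @param val_frac_of_trainval fraction of the train+validation pool used for
#'   validation.
#' @return a list of class `dataset_split` with elements `train_ids`,
#'   `val_ids`, `test_ids` and `seed`.
#' @export
split_dataset <- function(ids, seed, test_frac = 0.2,
                          val_frac_of_trainval = 0.1) {
  ids <- as.character(ids)
  if (!length(ids)) stop("empty id list")
  if (anyDuplicated(ids)) stop("duplicate ids in input")
  stopifnot(test_frac > 0, test_frac < 1,
            val_frac_of_trainval > 0, val_frac_of_trainval < 1)
  n <- length(ids)
  shuffled <- with_seed(seed, sample(sort(ids)))
  n_trainval <- floor(n * (1 - test_frac))
  n_train <- floor(n_trainval * (1 - val_frac_of_trainval))
  structure(
    list(train_ids = shuffled[seq_len(n_train)],
         val_ids = shuffled[n_train + seq_len(n_trainval - n_train)],
         test_ids = shuffled[n_trainval + seq_len(n - n_trainval)],
         seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

# Evaluate `expr` under a private RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
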