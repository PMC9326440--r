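# Synthetic-data generators: annotation sets with the study's box-size
# structure, noisy detections with known error rates, and stochastic
# flower-fate event logs.  Everything is seeded; identical seeds give
# identical output.

#' Simulate VOC-style annotation sets
#'
#' Draws ground-truth bounding boxes whose pixel areas follow a mixture
#' over the small/medium/large strata of [classify_size()] (thresholds
#' 32x32 and 96x96 px) and whose image-area fractions stay within
#' `(0, max_area_fraction]` — by default 0.25, the range observed for the
#' study's training annotations.  Aspect ratios (h/w) are drawn around the
#' published triple (0.75, 1.8, 3.2) with lognormal jitter, and areas are
#' log-uniform within their stratum, reproducing the small-target-heavy
#' area histogram.
#'
#' @param n_images number of images to simulate.
#' @param seed integer RNG seed.
#' @param boxes_per_image expected boxes per image (Poisson mean; at least
#'   one box is always drawn).
#' @param size_mixture length-3 probability vector over
#'   (small, medium, large), summing to 1.
#' @param width,height image dimensions in pixels.
#' @param max_area_fraction cap on box area as a fraction of the image.
#' @param aspect_ratios center values for the h/w ratio mixture.
#' @param ratio_sdlog lognormal sd of the ratio jitter.
#' @param label_probs named probability vector over class labels.
#' @return list of [image_annotation()] objects.
#' @export
simulate_annotations <- function(n_images, seed = 1L,
                                 boxes_per_image = 4,
                                 size_mixture = c(0.5, 0.35, 0.15),
                                 width = 640, height = 640,
                                 max_area_fraction = 0.25,
                                 aspect_ratios = c(0.75, 1.8, 3.2),
                                 ratio_sdlog = 0.15,
                                 label_probs = c(flower = 0.5, pod = 0.5)) {
  stopifnot(n_images >= 1, boxes_per_image > 0, length(size_mixture) == 3)
  if (abs(sum(size_mixture) - 1) > 1e-8) {
    stop("size_mixture weights must sum to 1")
  }
  max_area <- max_area_fraction * width * height
  strata <- list(small = c(1, 1024), medium = c(1024, 9216),
                 large = c(9216, max_area))
  for (s in which(size_mixture > 0)) {
    b <- strata[[s]]
    if (b[1] >= b[2]) {
      stop("stratum '", names(strata)[s], "' infeasible for ",
           width, "x", height, " at max_area_fraction ", max_area_fraction)
    }
  }
  with_seed(seed, {
    lapply(seq_len(n_images), function(i) {
      n_boxes <- max(1L, stats::rpois(1, boxes_per_image))
      rows <- lapply(seq_len(n_boxes), function(b) {
        stratum <- sample.int(3L, 1, prob = size_mixture)
        lim <- strata[[stratum]]
        # log-uniform within the stratum; keep strictly inside open bounds
        # so classify_size() returns exactly the requested stratum
        lo <- if (stratum == 2) lim[1] * 1.0001 else lim[1]
        hi <- if (stratum == 2) lim[2] * 0.9999 else lim[2]
        area <- exp(stats::runif(1, log(lo), log(hi)))
        ratio <- sample(aspect_ratios, 1) *
          stats::rlnorm(1, 0, ratio_sdlog)
        w <- sqrt(area / ratio)
        h <- sqrt(area * ratio)
        if (h > height) { h <- height; w <- area / h }
        if (w > width) { w <- width; h <- area / w }
        x0 <- stats::runif(1, 0, width - w)
        y0 <- stats::runif(1, 0, height - h)
        data.frame(x_min = x0, y_min = y0, x_max = x0 + w, y_max = y0 + h,
                   label = sample(names(label_probs), 1, prob = label_probs),
                   confidence = NA_real_, stringsAsFactors = FALSE)
      })
      image_annotation(sprintf("sim_%04d", i), width, height,
                       do.call(rbind, rows))
    })
  })
}

#' Detection-noise configuration
#'
#' Parameters of the stand-in detector used in place of a trained CNN:
#' each true box is missed independently with `p_miss`, survivors get
#' per-coordinate Gaussian jitter, and spurious boxes arrive per image as
#' Poisson(`p_spurious_per_image`) with sizes resampled from the true-box
#' population (so false positives are not trivially separable by shape).
#' True-positive confidences are Beta(`conf_tp[1]`, `conf_tp[2]`) and
#' false-positive confidences Beta(`conf_fp[1]`, `conf_fp[2]`); the
#' defaults (Beta(5,1) vs Beta(1,3)) make confidence ranking informative.
#'
#' @param p_miss miss probability in `[0, 1)`.
#' @param p_spurious_per_image expected spurious boxes per image, `>= 0`.
#' @param jitter_sd per-coordinate jitter sd in pixels, `>= 0`.
#' @param conf_tp,conf_fp Beta shape pairs for TP and FP confidences.
#' @param seed integer RNG seed.
#' @return a list of class `detection_noise_config`.
#' @export
detection_noise_config <- function(p_miss = 0, p_spurious_per_image = 0,
                                   jitter_sd = 0, conf_tp = c(5, 1),
                                   conf_fp = c(1, 3), seed = 1L) {
  stopifnot(p_miss >= 0, p_miss < 1, p_spurious_per_image >= 0,
            jitter_sd >= 0, length(conf_tp) == 2, length(conf_fp) == 2)
  structure(
    list(p_miss = p_miss, p_spurious_per_image = p_spurious_per_image,
         jitter_sd = jitter_sd, conf_tp = conf_tp, conf_fp = conf_fp,
         seed = as.integer(seed)),
    class = "detection_noise_config"
  )
}

empty_detections <- function() {
  data.frame(image_id = character(), label = character(),
             x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(),
             confidence = numeric(), stringsAsFactors = FALSE)
}

#' Simulate detector output over ground-truth annotations
#'
#' Applies the noise model of [detection_noise_config()] to a list of
#' ground-truth annotations and returns the detection table together with
#' the hidden provenance of every detection (true positive vs spurious),
#' so the evaluator can be validated against known error rates.  With an
#' all-zero noise config every true box is emitted at its exact position,
#' so position-based evaluation recovers precision = recall = 1.
#'
#' @param truth list of [image_annotation()] objects.
#' @param cfg a [detection_noise_config()].
#' @return a list: `detections` (table with columns `image_id`, `label`,
#'   `x_min`, `y_min`, `x_max`, `y_max`, `confidence`) and `is_true`
#'   (logical, TRUE for detections originating from a real box).
#' @export
simulate_detections <- function(truth, cfg) {
  stopifnot(inherits(cfg, "detection_noise_config"))
  pool <- do.call(rbind, lapply(truth, function(a) {
    b <- a$boxes
    if (!nrow(b)) return(NULL)
    data.frame(w = b$x_max - b$x_min, h = b$y_max - b$y_min,
               label = b$label, stringsAsFactors = FALSE)
  }))
  with_seed(cfg$seed, {
    out <- lapply(truth, function(a) {
      b <- a$boxes
      rows <- list()
      if (nrow(b)) {
        keep <- stats::runif(nrow(b)) >= cfg$p_miss
        bk <- b[keep, , drop = FALSE]
        if (nrow(bk)) {
          jit <- function(v) v + stats::rnorm(length(v), 0, cfg$jitter_sd)
          x1 <- jit(bk$x_min); x2 <- jit(bk$x_max)
          y1 <- jit(bk$y_min); y2 <- jit(bk$y_max)
          xmin <- pmax(0, pmin(x1, x2)); xmax <- pmin(a$width, pmax(x1, x2))
          ymin <- pmax(0, pmin(y1, y2)); ymax <- pmin(a$height, pmax(y1, y2))
          # guard against jitter collapsing a box at the image edge
          xmax <- pmax(xmax, xmin + 0.5); ymax <- pmax(ymax, ymin + 0.5)
          xmax <- pmin(xmax, a$width); ymax <- pmin(ymax, a$height)
          xmin <- pmin(xmin, xmax - 0.5); ymin <- pmin(ymin, ymax - 0.5)
          rows$tp <- data.frame(
            image_id = a$image_id, label = bk$label,
            x_min = xmin, y_min = ymin, x_max = xmax, y_max = ymax,
            confidence = stats::rbeta(nrow(bk), cfg$conf_tp[1],
                                      cfg$conf_tp[2]),
            is_true = TRUE, stringsAsFactors = FALSE)
        }
      }
      n_fp <- stats::rpois(1, cfg$p_spurious_per_image)
      if (n_fp > 0 && !is.null(pool) && nrow(pool)) {
        pick <- sample.int(nrow(pool), n_fp, replace = TRUE)
        w <- pmin(pool$w[pick], a$width)
        h <- pmin(pool$h[pick], a$height)
        x0 <- stats::runif(n_fp, 0, a$width - w)
        y0 <- stats::runif(n_fp, 0, a$height - h)
        rows$fp <- data.frame(
          image_id = a$image_id, label = pool$label[pick],
          x_min = x0, y_min = y0, x_max = x0 + w, y_max = y0 + h,
          confidence = stats::rbeta(n_fp, cfg$conf_fp[1], cfg$conf_fp[2]),
          is_true = FALSE, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
    dets <- do.call(rbind, out)
    if (is.null(dets)) {
      dets <- cbind(empty_detections(), is_true = logical())
    }
    rownames(dets) <- NULL
    list(detections = dets[, setdiff(names(dets), "is_true"), drop = FALSE],
         is_true = dets$is_true)
  })
}

#' Phenology-simulation configuration
#'
#' Study-condition defaults: 6 observed plants (three per cultivar in the
#' source study) of 15 main-stem nodes, the 2019 R1-R8 calendar of
#' [default_stage_calendar()], stage-dependent flower-opening intensities
#' that concentrate bloom in R1-R4, and fate probabilities
#' (flower drop 0.625, pod drop 0.205, pod survival 0.17) matching an
#' overall flower-drop rate near 62% with roughly 55% of formed pods
#' dropping.
#'
#' @param n_plants number of plants.
#' @param n_nodes main-stem nodes per plant.
#' @param calendar a [stage_calendar()].
#' @param intensity named vector, expected newly opened flowers per node
#'   per day, by the stage of the day; stages absent from the vector get 0.
#' @param fate_probs length-3 probability vector
#'   (flower_drop, pod_drop, pod_survive) summing to 1.
#' @param flower_drop_lag mean days from opening to flower drop.
#' @param pod_form_lag mean days from opening to pod formation.
#' @param pod_drop_lag mean days from pod formation to pod drop.
#' @param seed integer RNG seed.
#' @return a list of class `phenology_sim_config`.
#' @export
phenology_sim_config <- function(n_plants = 6L, n_nodes = 15L,
                                 calendar = default_stage_calendar(),
                                 intensity = c(R1 = 0.3, R2 = 0.5, R3 = 0.4,
                                               R4 = 0.2, R5 = 0.05),
                                 fate_probs = c(flower_drop = 0.625,
                                                pod_drop = 0.205,
                                                pod_survive = 0.17),
                                 flower_drop_lag = 5, pod_form_lag = 7,
                                 pod_drop_lag = 14, seed = 1L) {
  stopifnot(n_plants >= 1, n_nodes >= 1, inherits(calendar, "stage_calendar"),
            length(fate_probs) == 3, all(fate_probs >= 0),
            all(intensity >= 0), flower_drop_lag >= 0, pod_form_lag >= 0,
            pod_drop_lag >= 0)
  if (abs(sum(fate_probs) - 1) > 1e-8) stop("fate probabilities must sum to 1")
  window <- as.numeric(diff(range(calendar$start_date)))
  if (window < pod_form_lag + pod_drop_lag) {
    stop("calendar window shorter than the flower-to-pod-drop lag")
  }
  structure(
    list(n_plants = as.integer(n_plants), n_nodes = as.integer(n_nodes),
         calendar = calendar, intensity = intensity,
         fate_probs = fate_probs, flower_drop_lag = flower_drop_lag,
         pod_form_lag = pod_form_lag, pod_drop_lag = pod_drop_lag,
         seed = as.integer(seed)),
    class = "phenology_sim_config"
  )
}

#' Simulate a flower-fate event log
#'
#' Draws newly opened flowers per node per day from a Poisson with the
#' stage-dependent intensity, assigns each flower one of the three fates
#' (drop as a flower, form a pod that drops, form a pod that survives)
#' from the configured probability vector, and schedules the downstream
#' events with Poisson-distributed lags, clamped to the calendar window so
#' the log is conservation-complete: every opened flower is resolved by
#' the end of the window and [tally_fates()] recovers the hidden fate
#' tally exactly.
#'
#' @param cfg a [phenology_sim_config()].
#' @return event-log data frame (`plant_id`, `node_index`, `date`,
#'   `event_type`), sorted by date, with attribute `"true_fates"` — the
#'   simulator's hidden tally `c(flower_drop =, pod_drop =, pod_survive =)`.
#' @export
simulate_phenology <- function(cfg) {
  stopifnot(inherits(cfg, "phenology_sim_config"))
  cal <- cfg$calendar
  first <- cal$start_date[1]
  last <- cal$start_date[nrow(cal)]
  days <- seq(first, last, by = "day")
  day_stage <- stage_of_date(days, cal)
  lambda <- ifelse(day_stage %in% names(cfg$intensity),
                   cfg$intensity[day_stage], 0)
  fates <- names(cfg$fate_probs)
  with_seed(cfg$seed, {
    recs <- list()
    tally <- stats::setNames(numeric(3), fates)
    for (p in seq_len(cfg$n_plants)) {
      pid <- sprintf("plant_%02d", p)
      for (node in seq_len(cfg$n_nodes)) {
        n_new <- stats::rpois(length(days), lambda)
        for (d in which(n_new > 0)) {
          for (f in seq_len(n_new[d])) {
            open_day <- days[d]
            fate <- sample(fates, 1, prob = cfg$fate_probs)
            tally[fate] <- tally[fate] + 1
            ev <- data.frame(plant_id = pid, node_index = node,
                             date = open_day, event_type = "flower_open",
                             stringsAsFactors = FALSE)
            clamp <- function(date) min(date, last)
            if (fate == "flower_drop") {
              drop_day <- clamp(open_day + 1 +
                                  stats::rpois(1, cfg$flower_drop_lag))
              ev <- rbind(ev, data.frame(plant_id = pid, node_index = node,
                                         date = drop_day,
                                         event_type = "flower_drop",
                                         stringsAsFactors = FALSE))
            } else {
              form_day <- clamp(open_day + 1 +
                                  stats::rpois(1, cfg$pod_form_lag))
              ev <- rbind(ev, data.frame(plant_id = pid, node_index = node,
                                         date = form_day,
                                         event_type = "pod_form",
                                         stringsAsFactors = FALSE))
              if (fate == "pod_drop") {
                drop_day <- clamp(form_day + 1 +
                                    stats::rpois(1, cfg$pod_drop_lag))
                ev <- rbind(ev, data.frame(plant_id = pid, node_index = node,
                                           date = drop_day,
                                           event_type = "pod_drop",
                                           stringsAsFactors = FALSE))
              }
            }
            recs[[length(recs) + 1]] <- ev
          }
        }
      }
    }
    events <- do.call(rbind, recs)
    if (is.null(events)) {
      events <- data.frame(plant_id = character(), node_index = integer(),
                           date = as.Date(character()),
                           event_type = character(), stringsAsFactors = FALSE)
    }
    events <- events[order(events$date, events$plant_id, events$node_index), ]
    rownames(events) <- NULL
    attr(events, "true_fates") <- tally
    events
  })
}
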