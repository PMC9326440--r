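# Flower/pod fate statistics across soybean reproductive stages R1-R8:
# drop rates sharing the TNOFD+TNOPD+TNOPF denominator, per-stage drop
# breakdowns, node-layer distributions, and daily standing counts.

EVENT_TYPES <- c("flower_open", "flower_drop", "pod_form", "pod_drop")

validate_events <- function(events) {
  need <- c("plant_id", "node_index", "date", "event_type")
  missing <- setdiff(need, names(events))
  if (length(missing)) {
    stop("event log lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad)) {
    stop("unknown event type(s): ", paste(bad, collapse = ", "))
  }
  events$date <- as.Date(events$date)
  if (anyNA(events$date)) stop("unparseable date in event log")
  events
}

#' Reproductive-stage calendar
#'
#' Ordered boundary dates for the soybean reproductive stages R1 (start of
#' flowering) through R8 (full maturity).  The stage of a date is the last
#' boundary at or before it; dates before R1 are invalid.
#'
#' @param start_dates vector of 8 strictly increasing dates (coercible by
#'   `as.Date`), one per stage R1..R8.
#' @param stages stage names, default `R1`..`R8`.
#' @return a data frame of class `stage_calendar` with columns `stage`,
#'   `start_date`.
#' @export
stage_calendar <- function(start_dates, stages = paste0("R", seq_along(start_dates))) {
  start_dates <- as.Date(start_dates)
  stopifnot(length(start_dates) >= 2, length(stages) == length(start_dates))
  if (any(diff(start_dates) <= 0)) {
    stop("stage boundary dates must be strictly increasing")
  }
  structure(
    data.frame(stage = as.character(stages), start_date = start_dates,
               stringsAsFactors = FALSE),
    class = c("stage_calendar", "data.frame")
  )
}

#' Default stage calendar for the 2019 observation season
#'
#' The observation window ran from first flowering on 25 June 2019 (R1) to
#' full maturity on 30 September 2019 (R8); intermediate boundaries are
#' spaced at agronomically typical intervals within that window.
#'
#' @return a [stage_calendar()].
#' @export
default_stage_calendar <- function() {
  stage_calendar(as.Date(c("2019-06-25", "2019-07-05", "2019-07-15",
                           "2019-07-28", "2019-08-10", "2019-08-25",
                           "2019-09-10", "2019-09-30")))
}

#' Stage of one or more dates
#'
#' @param dates dates (coercible by `as.Date`).
#' @param cal a [stage_calendar()].
#' @return character vector of stage names.
#' @export
stage_of_date <- function(dates, cal) {
  stopifnot(inherits(cal, "stage_calendar"))
  dates <- as.Date(dates)
  idx <- findInterval(as.numeric(dates), as.numeric(cal$start_date))
  if (any(idx == 0)) {
    stop("date(s) before the first stage boundary (",
         format(cal$start_date[1]), ")")
  }
  cal$stage[idx]
}

#' Tally flower fates from a complete event log
#'
#' In a complete log every opened flower resolves to exactly one of: drop
#' as a flower (TNOFD), form a pod that later drops (TNOPD), or form a pod
#' that survives (TNOPF).  Hence `TNOFD + TNOPD + TNOPF` equals the number
#' of flowers opened — the shared denominator of the three fate rates.
#'
#' @param events event log: columns `plant_id`, `node_index`, `date`,
#'   `event_type` in `flower_open`, `flower_drop`, `pod_form`, `pod_drop`.
#' @return a list of class `fate_counts`: `tnofd`, `tnopd`, `tnopf`,
#'   `n_flowers` (flowers opened).
#' @export
tally_fates <- function(events) {
  events <- validate_events(events)
  n_open <- sum(events$event_type == "flower_open")
  tnofd <- sum(events$event_type == "flower_drop")
  n_form <- sum(events$event_type == "pod_form")
  tnopd <- sum(events$event_type == "pod_drop")
  if (tnopd > n_form) stop("more pod_drop than pod_form events")
  structure(
    list(tnofd = tnofd, tnopd = tnopd, tnopf = n_form - tnopd,
         n_flowers = n_open),
    class = "fate_counts"
  )
}

#' @export
print.fate_counts <- function(x, ...) {
  cat(sprintf(
    "<fate_counts> flowers dropped %d, pods dropped %d, pods formed %d (flowers opened %d)\n",
    x$tnofd, x$tnopd, x$tnopf, x$n_flowers))
  invisible(x)
}

#' Flower drop, pod drop and pod formation rates
#'
#' The three fates of an opened flower, as percentages of the shared
#' denominator `TNOFD + TNOPD + TNOPF` (total flowers dropped + total pods
#' dropped + total pods formed):
#' `FDR = TNOFD / sum * 100`, `PDR = TNOPD / sum * 100`,
#' `PFR = TNOPF / sum * 100`.  The triple sums to exactly 100 before
#' rounding.
#'
#' @param fc a [tally_fates()] result, or `tnofd` when the three counts are
#'   given separately.
#' @param tnopd,tnopf pod-drop and pod-formation counts when `fc` is a bare
#'   count.
#' @return named numeric vector `c(fdr =, pdr =, pfr =)` in percent.
#' @examples
#' fate_rates(10, 5, 5) # 50 25 25
#' @export
fate_rates <- function(fc, tnopd = NULL, tnopf = NULL) {
  if (inherits(fc, "fate_counts")) {
    tnofd <- fc$tnofd; tnopd <- fc$tnopd; tnopf <- fc$tnopf
  } else {
    tnofd <- fc
    stopifnot(!is.null(tnopd), !is.null(tnopf))
  }
  if (any(c(tnofd, tnopd, tnopf) < 0)) stop("counts must be non-negative")
  denom <- tnofd + tnopd + tnopf
  if (denom <= 0) stop("zero denominator: no resolved flowers")
  c(fdr = 100 * tnofd / denom,
    pdr = 100 * tnopd / denom,
    pfr = 100 * tnopf / denom)
}

#' Flower drop rate from two printed counts
#'
#' `dropped / total * 100`, the arithmetic of the per-sample flower-drop
#' column (e.g. 110 of 221 flowers gives 49.77%).  Coincides with the FDR
#' of [fate_rates()] when `total` is the shared fate denominator.
#'
#' @param dropped number of flowers dropped, `0 <= dropped <= total`.
#' @param total total number of flowers, positive.
#' @return percentage.
#' @export
flower_drop_rate <- function(dropped, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(dropped < 0) || any(dropped > total)) {
    stop("need 0 <= dropped <= total")
  }
  100 * dropped / total
}

#' Organ-conditional drop rate
#'
#' The rate `b / (a + b) * 100` over two organ counts — the arithmetic that
#' every printed per-sample pod-drop rate satisfies when `a` is the first
#' and `b` the second printed count column.  Provided alongside the strict
#' shared-denominator [fate_rates()] because the two published count
#' columns are mutually inconsistent with the shared-denominator formula
#' under their printed labels; neither reading is asserted as intended.
#'
#' @param a,b non-negative counts with `a + b > 0`.
#' @return percentage.
#' @export
organ_drop_rate <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  if (any(a + b <= 0)) stop("zero denominator")
  100 * b / (a + b)
}

#' Per-stage breakdown of drop events
#'
#' Attributes each drop event of `drop_type` to the stage interval
#' `[Rk, Rk+1)` containing its date and reports, per interval, the count
#' and its percentage of all drops of that type, plus the overall rate
#' (drops over organs produced: flowers opened for `flower_drop`, pods
#' formed for `pod_drop`).  Percentages are reported raw; rounded at 2 dp
#' they sum to 100 within 0.05.
#'
#' @param events event log (see [tally_fates()]).
#' @param cal a [stage_calendar()].
#' @param drop_type `"flower_drop"` or `"pod_drop"`.
#' @return a list of class `stage_breakdown`: `per_stage` (data frame
#'   `interval`, `n`, `percent`), `total_drops`, `overall_rate`.
#' @export
stage_breakdown <- function(events, cal, drop_type = c("flower_drop", "pod_drop")) {
  drop_type <- match.arg(drop_type)
  events <- validate_events(events)
  stopifnot(inherits(cal, "stage_calendar"))
  stage_of_date(events$date, cal) # validates window
  drops <- events[events$event_type == drop_type, , drop = FALSE]
  n_stage <- nrow(cal)
  intervals <- paste0(cal$stage[-n_stage], "~", cal$stage[-1])
  idx <- findInterval(as.numeric(drops$date), as.numeric(cal$start_date))
  idx <- pmin(idx, n_stage - 1L) # dates at/after the last boundary close the final interval
  counts <- tabulate(idx, n_stage - 1L)
  total <- nrow(drops)
  percent <- if (total > 0) 100 * counts / total else rep(0, n_stage - 1L)
  source_type <- if (drop_type == "flower_drop") "flower_open" else "pod_form"
  n_source <- sum(events$event_type == source_type)
  overall <- if (n_source > 0) 100 * total / n_source else NA_real_
  structure(
    list(per_stage = data.frame(interval = intervals, n = counts,
                                percent = percent, stringsAsFactors = FALSE),
         total_drops = total, n_source = n_source, overall_rate = overall,
         drop_type = drop_type),
    class = "stage_breakdown"
  )
}

#' @export
print.stage_breakdown <- function(x, ...) {
  cat(sprintf("<stage_breakdown> %s: %d drops of %d organs (rate %.2f%%)\n",
              x$drop_type, x$total_drops, x$n_source,
              if (is.na(x$overall_rate)) NA else x$overall_rate))
  df <- x$per_stage
  df$percent <- sprintf("%.2f%%", df$percent)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Divide main-stem nodes into lower/middle/upper layers
#'
#' Contiguous thirds from node 1 (the lowest) upward.  When the node count
#' is not divisible by 3 the remainder goes to the lowest layers first
#' (plants fill from the bottom), so 17 nodes give lower 1-6, middle 7-12,
#' upper 13-17.
#'
#' @param n_nodes number of main-stem nodes, at least 3.
#' @return factor of length `n_nodes` with levels `lower`, `middle`,
#'   `upper`; names are node indices.
#' @export
assign_layers <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3) stop("need at least 3 nodes to form three layers")
  base <- n_nodes %/% 3L
  r <- n_nodes %% 3L
  sizes <- rep(base, 3L) + as.integer(seq_len(3L) <= r)
  layers <- factor(rep(c("lower", "middle", "upper"), times = sizes),
                   levels = c("lower", "middle", "upper"))
  names(layers) <- seq_len(n_nodes)
  layers
}

#' Per-layer distribution of a per-node quantity
#'
#' Shares (percent, summing to 100) of a per-node count across the
#' lower/middle/upper layers of [assign_layers()].
#'
#' @param node_counts named numeric vector of counts, names are node
#'   indices; or an event log, in which case events of `event_type` are
#'   tallied per node.
#' @param layers a layer assignment from [assign_layers()].
#' @param event_type event type to tally when `node_counts` is a log.
#' @return named numeric vector `c(lower =, middle =, upper =)` in percent.
#' @export
spatial_distribution <- function(node_counts, layers,
                                 event_type = "flower_open") {
  if (is.data.frame(node_counts)) {
    ev <- validate_events(node_counts)
    ev <- ev[ev$event_type == event_type, , drop = FALSE]
    node_counts <- table(factor(ev$node_index, levels = names(layers)))
    node_counts <- stats::setNames(as.numeric(node_counts),
                                   names(layers))
  }
  nodes <- names(node_counts)
  if (is.null(nodes)) {
    if (length(node_counts) != length(layers)) {
      stop("unnamed counts must match the layer map length")
    }
    nodes <- names(layers)
  }
  if (!all(nodes %in% names(layers))) {
    stop("node(s) outside the layer map: ",
         paste(setdiff(nodes, names(layers)), collapse = ", "))
  }
  total <- sum(node_counts)
  if (total <= 0) stop("no counts to distribute")
  shares <- vapply(levels(layers), function(l) {
    sum(node_counts[nodes %in% names(layers)[layers == l]])
  }, numeric(1))
  100 * shares / total
}

#' Daily standing counts of open flowers and live pods
#'
#' Integrates an event log into day-by-day standing counts over the log's
#' date range: standing flowers on day t = opens up to t − flower drops up
#' to t − pod formations up to t (a flower stops being a flower when it
#' becomes a pod); standing pods = pod formations up to t − pod drops up to
#' t.  Both must stay non-negative everywhere, otherwise the log is
#' inconsistent and the offending date is reported.  Also returns the mean
#' daily count of newly opened flowers over the range and the peak
#' standing-flower day.
#'
#' @param events event log (see [tally_fates()]); may be empty.
#' @return a list of class `daily_series`: `series` (data frame `date`,
#'   `new_flowers`, `flowers`, `pods`), `mean_daily_flowers`, `peak_day`.
#' @export
daily_series <- function(events) {
  if (!nrow(events)) {
    return(structure(list(series = data.frame(date = as.Date(character()),
                                              new_flowers = integer(),
                                              flowers = integer(),
                                              pods = integer()),
                          mean_daily_flowers = NA_real_,
                          peak_day = as.Date(NA)),
                     class = "daily_series"))
  }
  events <- validate_events(events)
  days <- seq(min(events$date), max(events$date), by = "day")
  tally <- function(type) {
    d <- events$date[events$event_type == type]
    as.numeric(table(factor(as.character(d), levels = as.character(days))))
  }
  opens <- tally("flower_open")
  fdrops <- tally("flower_drop")
  forms <- tally("pod_form")
  pdrops <- tally("pod_drop")
  flowers <- cumsum(opens) - cumsum(fdrops) - cumsum(forms)
  pods <- cumsum(forms) - cumsum(pdrops)
  if (any(flowers < 0)) {
    stop("inconsistent log: standing flower count negative on ",
         format(days[which(flowers < 0)[1]]))
  }
  if (any(pods < 0)) {
    stop("inconsistent log: standing pod count negative on ",
         format(days[which(pods < 0)[1]]))
  }
  structure(
    list(series = data.frame(date = days, new_flowers = opens,
                             flowers = flowers, pods = pods),
         mean_daily_flowers = mean(opens),
         peak_day = days[which.max(flowers)]),
    class = "daily_series"
  )
}

#' @export
print.daily_series <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("<daily_series> %d day(s)", n))
  if (n) {
    cat(sprintf(", mean %.2f new flowers/day, peak standing flowers on %s",
                x$mean_daily_flowers, format(x$peak_day)))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.daily_series <- function(x, ...) {
  s <- x$series
  plot(s$date, s$flowers, type = "l", xlab = "date", ylab = "standing count",
       ylim = range(c(s$flowers, s$pods)), main = "Standing flowers and pods",
       ...)
  graphics::lines(s$date, s$pods, lty = 2)
  graphics::legend("topright", legend = c("flowers", "pods"), lty = 1:2,
                   bty = "n")
  invisible(x)
}
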