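# Build an event log whose flower drops are distributed over stage
# intervals according to integer counts (one drop per count unit, dated at
# each interval's start).
drops_by_stage <- function(counts, cal, type = "flower_drop") {
  do.call(rbind, lapply(seq_along(counts), function(k) {
    if (counts[k] == 0) return(NULL)
    ev("p1", 1, rep(cal$start_date[k], counts[k]), type)
  }))
}

test_that("fate rates share the TNOFD+TNOPD+TNOPF denominator and sum to 100", {
  expect_equal(fate_rates(10, 5, 5), c(fdr = 50, pdr = 25, pfr = 25))
  # published per-sample arithmetic: 196 flowers dropped of a 388 total
  r <- fate_rates(196, 100, 92)
  expect_equal(round(r[["fdr"]], 2), 50.52)
  expect_error(fate_rates(0, 0, 0), "denominator")

  set.seed(91)
  for (i in 1:25) {
    counts <- rpois(3, 40) + c(1, 0, 0)
    expect_equal(sum(fate_rates(counts[1], counts[2], counts[3])), 100)
  }
})

test_that("flower drop rate reproduces every printed per-sample cell", {
  for (i in seq_len(nrow(table6_counts))) {
    expect_equal(
      round(flower_drop_rate(table6_counts$dropped[i], table6_counts$total[i]), 2),
      table6_counts$rate[i],
      tolerance = 0.011)
  }
  expect_equal(flower_drop_rate(0, 50), 0)
  expect_error(flower_drop_rate(5, 4), "dropped")
  expect_error(flower_drop_rate(1, 0), "positive")
})

test_that("organ-conditional rate matches the printed pod-drop columns", {
  for (i in seq_len(nrow(table7_counts))) {
    expect_equal(
      round(organ_drop_rate(table7_counts$col1[i], table7_counts$col2[i]), 2),
      table7_counts$rate[i],
      tolerance = 0.011)
  }
  expect_error(organ_drop_rate(0, 0), "denominator")
})

test_that("stage calendar assigns dates to half-open intervals", {
  cal <- default_stage_calendar()
  expect_equal(stage_of_date("2019-06-25", cal), "R1")
  expect_equal(stage_of_date("2019-07-04", cal), "R1")
  expect_equal(stage_of_date("2019-07-05", cal), "R2")
  expect_equal(stage_of_date("2019-09-30", cal), "R8")
  expect_error(stage_of_date("2019-06-01", cal), "before")
  expect_error(stage_calendar(c("2019-07-01", "2019-06-01")), "increasing")
})

test_that("stage breakdown reproduces published rows from reconstructed counts", {
  cal <- default_stage_calendar()
  # HN51(1): 388 drop-events distributed (R1~R2 .. R5~R6) = 1,8,177,61,141
  hn1 <- drops_by_stage(c(1, 8, 177, 61, 141, 0, 0), cal)
  b1 <- stage_breakdown(hn1, cal, "flower_drop")
  expect_equal(round(b1$per_stage$percent[1:5], 2),
               c(0.26, 2.06, 45.62, 15.72, 36.34))
  # HN51(2): 294 events distributed 3,15,41,87,148
  hn2 <- drops_by_stage(c(3, 15, 41, 87, 148, 0, 0), cal)
  b2 <- stage_breakdown(hn2, cal, "flower_drop")
  expect_equal(round(b2$per_stage$percent[1:5], 2),
               c(1.02, 5.10, 13.95, 29.59, 50.34))
  expect_equal(sum(round(b2$per_stage$percent, 2)), 100, tolerance = 0.05)

  # all drops in one interval
  one <- drops_by_stage(c(0, 0, 5, 0, 0, 0, 0), cal)
  bo <- stage_breakdown(one, cal, "flower_drop")
  expect_equal(bo$per_stage$percent[3], 100)
  expect_equal(sum(bo$per_stage$percent[-3]), 0)

  # invariant to event order and to splitting by plant then merging
  set.seed(101)
  mixed <- rbind(drops_by_stage(c(2, 3, 9, 4, 7, 1, 2), cal),
                 ev("p2", 3, "2019-08-01", "flower_drop"))
  shuffled <- mixed[sample(nrow(mixed)), ]
  expect_equal(stage_breakdown(shuffled, cal)$per_stage,
               stage_breakdown(mixed, cal)$per_stage)
  by_plant <- lapply(split(mixed, mixed$plant_id), stage_breakdown, cal = cal)
  merged_n <- Reduce(`+`, lapply(by_plant, function(b) b$per_stage$n))
  expect_equal(merged_n, stage_breakdown(mixed, cal)$per_stage$n)
})

test_that("node layering splits contiguous thirds, remainder to the bottom", {
  l15 <- assign_layers(15)
  expect_equal(as.integer(table(l15)), c(5L, 5L, 5L))
  expect_equal(as.character(l15[c(1, 5, 6, 10, 11, 15)]),
               c("lower", "lower", "middle", "middle", "upper", "upper"))
  l17 <- assign_layers(17)
  expect_equal(as.character(l17[c(6, 7, 12, 13)]),
               c("lower", "middle", "middle", "upper"))
  expect_equal(as.integer(table(l17)), c(6L, 6L, 5L))
  expect_equal(as.integer(table(assign_layers(3))), c(1L, 1L, 1L))
  expect_error(assign_layers(2), "at least 3")
})

test_that("spatial distribution reports per-layer shares summing to 100", {
  layers <- assign_layers(15)
  counts <- setNames(rep(1, 15), 1:15)
  expect_equal(unname(spatial_distribution(counts, layers)),
               rep(100 / 3, 3))
  bottom <- setNames(c(9, rep(0, 14)), 1:15)
  expect_equal(spatial_distribution(bottom, layers)[["lower"]], 100)
  expect_equal(sum(spatial_distribution(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5,
                                          8, 9, 7, 9), layers)), 100)
  # event-log input tallies the chosen event type per node
  evl <- rbind(ev("p1", 2, "2019-07-01", "flower_open"),
               ev("p1", 14, "2019-07-02", "flower_open"),
               ev("p1", 14, "2019-07-03", "flower_drop"))
  sh <- spatial_distribution(evl, layers, "flower_open")
  expect_equal(unname(sh), c(50, 0, 50))
  expect_error(spatial_distribution(setNames(1, "99"), layers), "outside")
})

test_that("daily series does the standing-count bookkeeping", {
  # 1 open on day 1, drop on day 3 -> standing 1, 1, 0
  log1 <- rbind(ev("p1", 1, "2019-07-01", "flower_open"),
                ev("p1", 1, "2019-07-03", "flower_drop"))
  s1 <- daily_series(log1)
  expect_equal(s1$series$flowers, c(1, 1, 0))

  # open d1, pod_form d5, pod_drop d9
  log2 <- rbind(ev("p1", 1, "2019-07-01", "flower_open"),
                ev("p1", 1, "2019-07-05", "pod_form"),
                ev("p1", 1, "2019-07-09", "pod_drop"))
  s2 <- daily_series(log2)
  expect_equal(s2$series$flowers, c(1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(s2$series$pods, c(0, 0, 0, 0, 1, 1, 1, 1, 0))

  expect_equal(nrow(daily_series(log1[0, ])$series), 0)

  # inconsistent log: drop before any open
  bad <- rbind(ev("p1", 1, "2019-07-01", "flower_drop"),
               ev("p1", 1, "2019-07-02", "flower_open"))
  expect_error(daily_series(bad), "inconsistent log.*2019-07-01")
})

test_that("complete simulated logs conserve flower fates", {
  for (seed in c(5, 17)) {
    events <- simulate_phenology(phenology_sim_config(n_plants = 2, seed = seed))
    fc <- tally_fates(events)
    hidden <- attr(events, "true_fates")
    expect_equal(fc$tnofd, unname(hidden["flower_drop"]))
    expect_equal(fc$tnopd, unname(hidden["pod_drop"]))
    expect_equal(fc$tnopf, unname(hidden["pod_survive"]))
    expect_equal(fc$tnofd + fc$tnopd + fc$tnopf, fc$n_flowers)
    # a complete log also yields a consistent daily series
    expect_s3_class(daily_series(events), "daily_series")
  }
})
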