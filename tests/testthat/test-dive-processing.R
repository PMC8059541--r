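test_that("zero-offset correction removes constant and drifting offsets", {
  rec <- make_trapezoid_record(120, pad = 2400)   # 4 h at the surface
  shifted <- rec; shifted$depth_m <- shifted$depth_m + 2
  fixed <- zero_offset_correct(shifted)
  surf <- fixed$depth_m[rec$depth_m == 0]
  expect_true(all(abs(surf) <= 0.5))
  expect_equal(max(fixed$depth_m), max(rec$depth_m), tolerance = 0.5)

  # linear drift 0 -> 3 m over 24 h on a mostly-surface record
  t24 <- seq(0, 86400, by = 6)
  drift <- 3 * t24 / 86400
  rec24 <- data.frame(time = t24, depth_m = drift)
  fixed24 <- zero_offset_correct(rec24)
  expect_lt(max(abs(fixed24$depth_m)), 0.5)

  # an already-correct record is left essentially unchanged
  ok <- zero_offset_correct(rec)
  expect_true(all(abs(ok$depth_m - rec$depth_m) <= 0.5))

  expect_warning(zero_offset_correct(data.frame(time = 1:50 * 6,
                                                depth_m = rep(100, 50))),
                 "skipped")
})

test_that("dive detection finds constructed dives with exact boundaries", {
  rec <- make_trapezoid_record(120, flat_samples = 10)
  dv <- detect_dives(rec)
  expect_equal(nrow(dv), 1)
  expect_equal(dv$max_depth, 120)

  # two dives separated by 60 s at the surface
  r2 <- rbind(rec, within(rec, time <- time + max(rec$time) + 66))
  dv2 <- detect_dives(r2)
  expect_equal(nrow(dv2), 2)

  # nothing deep enough
  shallow <- rec; shallow$depth_m <- pmin(shallow$depth_m, 8)
  expect_equal(nrow(detect_dives(shallow)), 0)

  # a gap longer than 2x the sampling interval breaks the record
  gap <- rec
  mid <- which.max(gap$depth_m)
  gap <- gap[-(mid:(mid + 2)), ]
  dvg <- detect_dives(gap, min_duration = 0, min_depth = 5)
  expect_equal(nrow(dvg), 2)
})

test_that("bottom phase matches the closed-form geometry", {
  tri <- make_triangle_record(120, pad = 2)
  dv <- detect_dives(tri)
  i <- dv$start_idx:dv$end_idx
  bp <- compute_bottom_phase(tri$time[i], tri$depth_m[i])
  # at 1 m/s the 80% envelope of a 120 m triangle spans 96..144 s
  expect_equal(bp$bottom_duration, 48, tolerance = 6)

  flat <- make_trapezoid_record(120, flat_samples = 10)   # 60 s flat
  dvf <- detect_dives(flat)
  j <- dvf$start_idx:dvf$end_idx
  bpf <- compute_bottom_phase(flat$time[j], flat$depth_m[j])
  expect_gte(bpf$bottom_duration, 60)

  # only the apex qualifies -> zero-length bottom phase
  spike <- data.frame(time = c(0, 6, 12, 18, 24),
                      depth_m = c(0, 50, 100, 50, 0))
  bps <- compute_bottom_phase(spike$time, spike$depth_m)
  expect_equal(bps$bottom_duration, 0)
})

test_that("wiggle counting follows the reversal definition", {
  expect_equal(count_wiggles(c(100, 110, 120, 110, 100)), 0)  # V-shape
  expect_equal(count_wiggles(c(100, 98, 100, 97, 100)), 2)
  jitter <- 100 + rep(c(0, -0.5), 10)
  expect_equal(count_wiggles(jitter), 0)
  # invariant under depth offset
  x <- c(100, 97, 100, 96, 98, 95, 100)
  expect_equal(count_wiggles(x), count_wiggles(x + 50))
})

test_that("benthic classification follows the depth-ceiling and flatness rule", {
  base <- data.frame(
    seal_id = "s1",
    day = rep(1:10, each = 3),
    max_depth = 300, bottom_cv = 0.1, stringsAsFactors = FALSE)
  # one flat dive at the rolling maximum on day 5
  base$max_depth[14] <- 310; base$bottom_cv[14] <- 0.0
  # one wiggly mid-water dive well below the ceiling
  base$max_depth[20] <- 180; base$bottom_cv[20] <- 0.05
  cl <- classify_dives(base)
  expect_equal(cl$dive_class[14], "benthic")
  expect_equal(cl$dive_class[20], "pelagic")
  # without a day of history everything is pelagic and flagged
  d1 <- classify_dives(base[base$day == 1, ])
  expect_true(all(d1$dive_class == "pelagic"))
  expect_true(all(!d1$history_ok))
})

test_that("planted benthic dives are recovered at about their 1% rate", {
  sc <- season_scenario(n_seals = 4, days = 40, dives_per_day = 25,
                        shallow_start_day = 18, shallow_duration = 12,
                        ramp_days = 5, seed = 7)
  sim <- generate_tdr(sc)
  dives <- process_tdr(sim$records)
  frac <- mean(dives$dive_class == "benthic")
  expect_gt(frac, 0.003)
  expect_lt(frac, 0.03)
  m <- merge(dives, sim$truth, by = c("seal_id", "start"),
             suffixes = c("", ".t"))
  # essentially all planted benthic dives are found
  expect_gt(mean(m$dive_class[m$benthic] == "benthic"), 0.8)
})

test_that("benthic depth trend model recovers planted slopes and nulls", {
  set.seed(21)
  mk <- function(slope) {
    d <- expand.grid(seal_id = c("a", "b", "c"), day = 1:30)
    d$max_depth <- 380 + slope * d$day +
      c(a = -10, b = 0, c = 10)[d$seal_id] + rnorm(nrow(d), 0, 5)
    d
  }
  flat <- benthic_depth_trend(mk(0))
  expect_true(flat$covers_zero)
  trend <- benthic_depth_trend(mk(0.5))
  expect_lt(abs(trend$slope - 0.5), 2 * trend$se)
  expect_error(benthic_depth_trend(mk(0)[1:3, ]), "at least")
})

test_that("daily summaries compute the documented quantities and exclude benthic dives", {
  dv <- data.frame(
    seal_id = "s1", day = 1,
    max_depth = c(100, 200, 400), duration = c(600, 600, 600),
    bottom_duration = c(60, 60, 60), n_wiggles = c(1, 2, 0),
    dive_class = c("pelagic", "pelagic", "benthic"),
    stringsAsFactors = FALSE)
  s <- daily_summaries(dv)
  expect_equal(s$sealdays$mean_max_depth, 150)
  expect_equal(s$sealdays$n_dives, 2)
  expect_equal(s$sealdays$wiggle_rate, 3 / 2)   # 3 wiggles in 2 bottom-min
  expect_equal(s$sealdays$efficiency, 0.1)
  expect_true(all(s$sealdays$efficiency >= 0 & s$sealdays$efficiency <= 1))
})

test_that("pipeline summaries equal generator truth summaries", {
  sc <- small_scenario(seed = 14)
  sim <- generate_tdr(sc)
  dives <- process_tdr(sim$records)
  got <- daily_summaries(dives)$sealdays
  want <- sim$sealdays
  key <- function(d) paste(d$seal_id, d$day)
  m <- match(key(want), key(got))
  expect_true(all(!is.na(m)))
  expect_equal(got$mean_max_depth[m], want$mean_max_depth, tolerance = 0.01)
  expect_equal(got$wiggle_rate[m], want$wiggle_rate, tolerance = 0.02)
  expect_equal(got$efficiency[m], want$efficiency, tolerance = 0.01)
})

test_that("processing is invariant to splitting a record at a surface interval", {
  sc <- small_scenario(seed = 17, n_seals = 1, days = 3)
  sim <- generate_tdr(sc)
  rec <- sim$records
  cut <- which(rec$depth_m == 0 & rec$time > max(rec$time) / 2)[1]
  d_all <- detect_dives(rec)
  d_split <- rbind(detect_dives(rec[1:cut, ]),
                   detect_dives(rec[cut:nrow(rec), ]))
  expect_equal(nrow(d_all), nrow(d_split))
  expect_equal(sort(d_all$start), sort(d_split$start))
  expect_equal(sort(d_all$max_depth), sort(d_split$max_depth))
})

test_that("shallow-period dives concentrate above 200 m relative to deep periods", {
  sc <- season_scenario(seed = 19)
  sim <- generate_tdr(sc, signal = FALSE)
  tr <- shallow_period_truth(sc)
  p <- sim$truth[!sim$truth$benthic, ]
  deep_frac <- mean(p$max_depth[p$day < tr$start - 5] < 200)
  shal_frac <- mean(p$max_depth[p$day > tr$start & p$day < tr$end] < 200)
  expect_gt(shal_frac, deep_frac)
})
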