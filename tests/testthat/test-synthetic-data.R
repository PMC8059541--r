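test_that("scenario validation rejects impossible conditions", {
  expect_error(season_scenario(shallow_depth = 300), "shallower")
  expect_error(season_scenario(shallow_duration = -1), "positive")
  expect_error(season_scenario(n_seals = 0), "positive")
  expect_error(season_scenario(shallow_duration = 2, ramp_days = 20),
               "too short")
})

test_that("generated depth series are seeded-deterministic, quantized and on the 6 s grid", {
  sc <- small_scenario(seed = 4)
  a <- generate_tdr(sc)
  b <- generate_tdr(sc)
  expect_identical(a, b)
  expect_true(all(a$records$depth_m %% 0.5 == 0))
  expect_true(all(a$records$time %% 6 == 0))
  expect_true(all(diff(a$records$time[a$records$seal_id == "seal01"]) == 6))
  # truth is identical whether or not the signal is assembled
  expect_identical(generate_tdr(sc, signal = FALSE)$truth, a$truth)
})

test_that("day-averaged true depths track the scenario trajectory", {
  sc <- season_scenario(seed = 12)
  sim <- generate_tdr(sc, signal = FALSE)
  traj <- depth_trajectory(sc)
  daymean <- tapply(sim$sealdays$mean_max_depth, sim$sealdays$day, mean)
  err <- as.numeric(daymean) - traj[as.numeric(names(daymean))]
  # seal intercepts (sd 15) + day noise (sd 20) over 10 seals
  expect_lt(mean(abs(err)), 15)
  expect_gt(cor(as.numeric(daymean), traj[as.numeric(names(daymean))]), 0.9)
})

test_that("the trajectory spends exactly shallow_duration days at or below the threshold", {
  sc <- season_scenario()
  day <- seq(1, sc$days, by = 0.01)
  below <- depth_trajectory(sc, day) <= sc$shallow_threshold_m
  expect_equal(sum(below) * 0.01, sc$shallow_duration, tolerance = 0.01)
  tr <- shallow_period_truth(sc)
  expect_equal(tr$end - tr$start, sc$shallow_duration)
})

test_that("wiggle counts are planted at the expected depth-dependent rate", {
  sc <- season_scenario(seed = 31)
  sim <- generate_tdr(sc, signal = FALSE)
  p <- sim$truth[!sim$truth$benthic, ]
  rate <- p$n_wiggles / (p$bottom_duration / 60)
  expected <- sc$wiggle_intercept + sc$wiggle_slope * p$max_depth
  # pooled realized rate matches the planted linear law
  expect_equal(mean(rate), mean(expected), tolerance = 0.05)
  deep <- p$max_depth > 200; shal <- p$max_depth < 150
  expect_gt(mean(rate[shal]), mean(rate[deep]))
})

test_that("burst-free accelerometer records never cross the capture threshold", {
  sc <- small_scenario(seed = 3)
  sim <- generate_tdr(sc, signal = FALSE)
  acc <- generate_accel(sim$truth[1:4, ], capture_rate = 0, seed = 5)
  expect_equal(nrow(acc$events), 0)
  f <- highpass_surge(acc$records$surge_g)
  expect_lt(max(abs(f)), 0.3)
})

test_that("planted capture bursts are recovered exactly by the detector", {
  sc <- small_scenario(seed = 3)
  sim <- generate_tdr(sc, signal = FALSE)
  acc <- generate_accel(sim$truth[1:6, ], capture_rate = 1.2, seed = 8)
  expect_gt(nrow(acc$events), 0)
  f <- highpass_surge(acc$records$surge_g)
  ev <- detect_prey_captures(acc$records$time, f)
  expect_equal(nrow(ev), nrow(acc$events))
  # every planted burst matched by a detection within half a second
  expect_true(all(vapply(acc$events$time,
                         function(tm) any(abs(ev$time - tm) < 0.5),
                         logical(1))))
  expect_identical(generate_accel(sim$truth[1:6, ], capture_rate = 1.2,
                                  seed = 8)$records, acc$records)
})

test_that("ice generator plants break-out dates the detector recovers exactly", {
  bo <- c(Northeast = 30, North = 40, Northwest = 50, West = 60,
          Southwest = 70)
  ice <- generate_ice(bo, n_days = 100, seed = 2)
  for (nm in names(bo)) {
    cell <- ice[ice$cell_id == nm, ]
    d <- breakout_date(seq_len(nrow(cell)), cell$concentration_pct)
    expect_equal(d, unname(bo[nm]))
  }
  expect_true(all(ice$concentration_pct >= 0 & ice$concentration_pct <= 100))
  # anticlockwise ordering is preserved
  days <- vapply(names(bo), function(nm) {
    cell <- ice[ice$cell_id == nm, ]
    breakout_date(seq_len(nrow(cell)), cell$concentration_pct)
  }, numeric(1))
  expect_true(all(diff(days[c("Northeast", "North", "Northwest", "West",
                              "Southwest")]) > 0))
})

test_that("a never-declining cell reports no break-out", {
  ice <- generate_ice(c(Northeast = NA), n_days = 60,
                      cells = data.frame(name = "Northeast", lat = -77.24,
                                         lon = 169.10), seed = 3)
  expect_true(is.na(breakout_date(seq_len(60), ice$concentration_pct)))
})

test_that("refreeze episodes do not reset the first break-out date", {
  cells <- data.frame(name = "West", lat = -77.32, lon = 165.84)
  a <- generate_ice(c(West = 40), n_days = 100, cells = cells,
                    refreeze = TRUE, seed = 6)
  d <- breakout_date(seq_len(100), a$concentration_pct)
  expect_equal(d, 40)
})

test_that("isotope generator reproduces the target consumer signature and rejects bad proportions", {
  iso <- generate_isotopes(n_seals = 40, seed = 9)
  expect_equal(mean(iso$consumers$d15N), 13.0, tolerance = 0.3)
  expect_equal(mean(iso$consumers$d13C), -23.2, tolerance = 0.3)
  expect_error(generate_isotopes(true_p = c(0.5, 0.4, 0.05, 0.02, 0.02)),
               "sum to 1")
  tr <- isotope_trend(generate_isotopes(seed = 10)$whiskers)
  expect_true(tr$d15N$covers_zero)
  expect_true(tr$d13C$covers_zero)
})
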