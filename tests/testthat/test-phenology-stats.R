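make_sealdays <- function(f, n_seals = 4, days = 1:60, noise = 3,
                          seed = 1) {
  set.seed(seed)
  d <- expand.grid(seal_id = sprintf("s%d", seq_len(n_seals)), day = days,
                   stringsAsFactors = FALSE)
  d$mean_max_depth <- f(d$day) + rnorm(nrow(d), 0, noise)
  d
}

test_that("a constant depth series yields a flat curve with a narrow interval", {
  sd <- make_sealdays(function(x) 150, noise = 2)
  cv <- fit_seasonal_curve(sd)
  expect_true(all(abs(cv$eval$fit - 150) < 2))
  expect_true(all(cv$eval$hi - cv$eval$lo < 5))
  expect_true(all(cv$eval$lo <= cv$eval$fit & cv$eval$fit <= cv$eval$hi))
})

test_that("curve fitting errors on a single date and warns on a single seal", {
  one_date <- data.frame(seal_id = c("a", "b"), day = c(5, 5),
                         mean_max_depth = c(100, 120))
  expect_error(fit_seasonal_curve(one_date), "rank-deficient")
  single <- make_sealdays(function(x) 100 + x, n_seals = 1)
  expect_warning(fit_seasonal_curve(single), "single seal")
})

test_that("the fitted curve is invariant to seal relabeling and equivariant to depth shifts", {
  sd <- make_sealdays(function(x) 150 + x, seed = 3)
  a <- fit_seasonal_curve(sd)
  relab <- sd
  relab$seal_id <- chartr("1234", "4321", relab$seal_id)
  b <- fit_seasonal_curve(relab)
  expect_equal(a$eval$fit, b$eval$fit, tolerance = 1e-6)
  shifted <- sd; shifted$mean_max_depth <- shifted$mean_max_depth + 50
  c2 <- fit_seasonal_curve(shifted)
  expect_equal(c2$eval$fit, a$eval$fit + 50, tolerance = 1e-4)
})

test_that("synthetic seasonal trajectory minimum is recovered closely", {
  sc <- season_scenario(seed = 41)
  sim <- generate_tdr(sc, signal = FALSE)
  cv <- fit_seasonal_curve(sim$sealdays)
  sp <- extract_shallow_period(cv)
  tr <- shallow_period_truth(sc)
  expect_lt(abs(sp$shallowest_depth - sc$shallow_depth), 10)
  expect_lt(abs(sp$shallowest_x - tr$center), 5)
})

test_that("shallow-period extraction matches a closed-form parabola and a brute-force scan", {
  x <- seq(0, 40, by = 0.1)
  fit <- 100 + 0.4 * (x - 20)^2        # crosses 140 m at x = 10 and 30
  curve <- structure(list(eval = data.frame(x = x, fit = fit,
                                            lo = fit - 1, hi = fit + 1)),
                     class = "season_curve")
  sp <- extract_shallow_period(curve, 140)
  expect_equal(sp$start, 10, tolerance = 0.1)
  expect_equal(sp$end, 30, tolerance = 0.1)
  expect_equal(sp$duration, 20, tolerance = 0.2)
  expect_equal(sp$shallowest_x, 20, tolerance = 0.1)
  expect_equal(sp$shallowest_depth, 100, tolerance = 0.01)

  deep <- curve; deep$eval$fit <- deep$eval$fit + 200
  expect_null(extract_shallow_period(deep, 140))

  # brute-force equivalence on random curves
  set.seed(7)
  for (i in 1:50) {
    f <- 150 + cumsum(rnorm(100, 0, 4))
    cr <- structure(list(eval = data.frame(x = 1:100, fit = f,
                                           lo = f, hi = f)),
                    class = "season_curve")
    sp2 <- extract_shallow_period(cr, 140)
    below <- which(f <= 140)
    if (!length(below)) {
      expect_null(sp2)
    } else {
      runs <- split(below, cumsum(c(1, diff(below) != 1)))
      lens <- vapply(runs, function(r) max(r) - min(r), numeric(1))
      best <- runs[[which.max(lens)]]
      expect_equal(sp2$start, min(best))
      expect_equal(sp2$end, max(best))
      expect_equal(sp2$shallowest_depth, min(f[best]))
    }
  }
})

test_that("cross-year regression matches hand-computed OLS with a one-tailed p", {
  pts <- data.frame(date = c(10, 20, 30, 40), depth = c(21, 41, 61, 81))
  r <- suppressWarnings(cross_year_regression(pts))
  expect_equal(r$slope, 2); expect_equal(r$intercept, 1)
  expect_equal(r$r2, 1)

  set.seed(9)
  pts2 <- data.frame(date = c(3, 11, 19, 27),
                     depth = c(120, 140, 133, 155))
  r2 <- cross_year_regression(pts2)
  o <- oracle_ols(pts2$date, pts2$depth)
  expect_equal(r2$slope, o$slope)
  expect_equal(r2$intercept, o$intercept)
  expect_equal(r2$r2, o$r2)
  tval <- r2$slope / r2$se
  expect_equal(r2$p, pt(tval, 2, lower.tail = FALSE))
  expect_error(cross_year_regression(pts[1:2, ]), "at least 3")
})

test_that("one-tailed p is uniform under a slope-0 truth", {
  set.seed(15)
  ps <- replicate(300, {
    pts <- data.frame(date = c(5, 15, 25, 35), depth = rnorm(4, 120, 10))
    cross_year_regression(pts)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("wiggle-depth regression recovers exact and planted relationships", {
  daily <- data.frame(mean_max_depth = seq(100, 250, length.out = 20))
  daily$wiggle_rate <- 3.2589 - 0.0043 * daily$mean_max_depth
  r <- suppressWarnings(wiggle_depth_regression(daily))
  expect_equal(r$slope, -0.0043)
  expect_equal(r$r2, 1)
  expect_error(wiggle_depth_regression(
    data.frame(mean_max_depth = rep(150, 20), wiggle_rate = 1:20 / 10)),
    "zero-variance")
  # destroying the pairing destroys the association
  set.seed(3)
  daily$wiggle_rate <- sample(daily$wiggle_rate + rnorm(20, 0, 0.05))
  rs <- wiggle_depth_regression(daily)
  expect_true(rs$ci[1] <= 0 && rs$ci[2] >= 0)
})

test_that("ancillary regression recovers planted slopes", {
  set.seed(11)
  x <- runif(12, 0, 3)
  r1 <- suppressWarnings(ancillary_regression(x, 2 + 0.5 * x))
  expect_equal(r1$r2, 1); expect_equal(r1$slope, 0.5)
  y <- 2 + 0.5 * x + rnorm(12, 0, 0.2)
  r2 <- ancillary_regression(x, y)
  expect_lt(abs(r2$slope - 0.5), 2 * r2$se)
  r0 <- ancillary_regression(x, rnorm(12))
  expect_true(r0$ci[1] <= 0 && r0$ci[2] >= 0)
  expect_error(ancillary_regression(1:2, 1:2), "at least 3")
})

test_that("period contrasts reproduce stated arithmetic and planted changes", {
  daily <- data.frame(day = 1:50)
  daily$wiggle_rate <- c(rep(2.0, 15), rep(2.32, 20), rep(2.06, 15))
  daily$efficiency <- c(rep(0.4, 15), rep(0.5, 20), rep(0.45, 15))
  sp <- list(start = 16, end = 35)
  pc <- period_contrasts(daily, sp)
  expect_equal(pc$feed_early_to_shallow_pct, 16)
  expect_equal(pc$feed_shallow_to_late_pct, 100 * (2.06 - 2.32) / 2.32)
  expect_equal(pc$eff_early_to_shallow_pct, 25)
  expect_equal(pc$compound_efficiency_pct, 100 * (1.16 * 1.25 - 1))

  same <- daily
  same$wiggle_rate <- 2; same$efficiency <- 0.5
  pc0 <- period_contrasts(same, sp)
  expect_equal(pc0$feed_early_to_shallow_pct, 0)
  expect_equal(pc0$compound_efficiency_pct, 0)

  expect_warning(period_contrasts(daily[10:50, ], sp), "flank")
})

test_that("planted wiggle-rate period contrasts are recovered from generator truth", {
  sc <- season_scenario(seed = 43)
  sim <- generate_tdr(sc, signal = FALSE)
  d <- daily_summaries(within(sim$truth,
                              dive_class <- ifelse(benthic, "benthic",
                                                   "pelagic")))$daily
  tr <- shallow_period_truth(sc)
  pc <- period_contrasts(d, list(start = tr$start, end = tr$end))
  r <- function(dep) sc$wiggle_intercept + sc$wiggle_slope * dep
  # expected contrast from the planted linear law and the trajectory
  expect_lt(abs(pc$feed_early_to_shallow_pct -
                  100 * (r(110) / r(233) - 1)), 3)
})

test_that("AIC covariate comparison identifies the generating mechanism", {
  sim_years <- function(arrivals, seed0, driven) {
    out <- list()
    for (y in seq_along(arrivals)) {
      s0 <- if (driven == "arrival") arrivals[y] + 5 else 45
      sc <- season_scenario(shallow_start_day = s0, seed = seed0 + y)
      sd <- generate_tdr(sc, signal = FALSE)$sealdays
      sd$year <- y
      sd$seal_id <- paste0("y", y, "_", sd$seal_id)
      out[[y]] <- sd
    }
    do.call(rbind, out)
  }
  arr <- data.frame(source = "West", velocity = 10.3, year = 1:2,
                    arrival_day = c(30, 50))
  sd_arr <- sim_years(c(30, 50), 100, "arrival")
  cc <- compare_covariates(sd_arr, arr)
  expect_gt(cc$delta_aic, 0)
  sd_cal <- sim_years(c(30, 50), 200, "calendar")
  cc2 <- compare_covariates(sd_cal, arr)
  expect_lt(cc2$delta_aic, 0)
  # identical arrivals across years: designs differ only by a shift
  arr0 <- data.frame(source = "West", velocity = 10.3, year = 1:2,
                     arrival_day = c(40, 40))
  cc3 <- compare_covariates(sd_cal, arr0)
  expect_lt(abs(cc3$delta_aic), 2)
  expect_error(compare_covariates(sd_cal[sd_cal$year == 1, ], arr),
               "at least 2 years")
})
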