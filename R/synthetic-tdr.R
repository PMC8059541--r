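#' Seasonal diving scenario
#'
#' Defines the conditions a synthetic deployment emulates: a population of
#' seals whose daily mean maximum dive depth follows a deep -> shallow -> deep
#' seasonal trajectory (deep early-summer diving near 233 m, a mid-summer
#' shallow plateau near 110 m lasting about 24 days, then deep diving near
#' 230 m again), with wiggle rates that decline linearly with depth.
#'
#' @param deep_depth_early mean maximum dive depth (m) in early summer.
#' @param shallow_depth mean maximum dive depth (m) during the shallow plateau.
#' @param deep_depth_late mean maximum dive depth (m) after the plateau.
#' @param shallow_start_day day-of-season on which the shallow plateau starts.
#' @param shallow_duration length of the shallowing period (days): the span
#'   over which the trajectory stays at or below `shallow_threshold_m`,
#'   which includes the sub-threshold parts of both ramps. The 110 m
#'   plateau length is derived from it.
#' @param shallow_threshold_m depth threshold defining the shallowing
#'   period (m).
#' @param ramp_days length of the linear transitions into and out of the
#'   plateau (days).
#' @param n_seals number of instrumented seals.
#' @param days length of the deployment (days).
#' @param dives_per_day expected number of dives per seal-day (Poisson mean).
#' @param wiggle_slope slope of the expected wiggle rate on mean dive depth
#'   (wiggles min^-1 m^-1).
#' @param wiggle_intercept intercept of the wiggle-rate relationship
#'   (wiggles min^-1).
#' @param seal_sd between-seal random-intercept SD (m).
#' @param day_sd seal-day level depth noise SD (m).
#' @param dive_sd dive-to-dive depth noise SD within a seal-day (m).
#' @param benthic_prob probability that a dive is a flat-bottomed benthic dive
#'   to the seal's local seabed depth.
#' @param benthic_depth seabed depth (m) for benthic dives.
#' @param start_date calendar date of day 1.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return A `season_scenario` object (named list).
#' @export
season_scenario <- function(deep_depth_early = 233,
                            shallow_depth = 110,
                            deep_depth_late = 230,
                            shallow_start_day = 45,
                            shallow_duration = 24,
                            shallow_threshold_m = 140,
                            ramp_days = 15,
                            n_seals = 10,
                            days = 100,
                            dives_per_day = 30,
                            wiggle_slope = -0.0043,
                            wiggle_intercept = 3.2589,
                            seal_sd = 15,
                            day_sd = 20,
                            dive_sd = 8,
                            benthic_prob = 0.01,
                            benthic_depth = 380,
                            start_date = as.Date("2016-11-01"),
                            seed = 1L) {
  sc <- list(deep_depth_early = deep_depth_early, shallow_depth = shallow_depth,
             deep_depth_late = deep_depth_late,
             shallow_start_day = shallow_start_day,
             shallow_duration = shallow_duration,
             shallow_threshold_m = shallow_threshold_m,
             ramp_days = ramp_days,
             n_seals = as.integer(n_seals), days = as.integer(days),
             dives_per_day = dives_per_day,
             wiggle_slope = wiggle_slope, wiggle_intercept = wiggle_intercept,
             seal_sd = seal_sd, day_sd = day_sd, dive_sd = dive_sd,
             benthic_prob = benthic_prob, benthic_depth = benthic_depth,
             start_date = as.Date(start_date), seed = as.integer(seed))
  depths <- c(deep_depth_early, shallow_depth, deep_depth_late, benthic_depth)
  if (any(depths <= 0)) stop("all depths must be positive")
  if (shallow_depth >= min(deep_depth_early, deep_depth_late))
    stop("shallow_depth must be shallower than both deep depths")
  if (shallow_duration <= 0) stop("shallow_duration must be positive")
  if (plateau_length(sc) <= 0)
    stop("shallow_duration too short for the ramp geometry: the ",
         "sub-threshold parts of the ramps already exceed it")
  if (sc$n_seals < 1L || sc$days < 1L || dives_per_day <= 0)
    stop("counts must be positive")
  if (benthic_prob < 0 || benthic_prob > 1)
    stop("benthic_prob must be in [0, 1]")
  structure(sc, class = "season_scenario")
}

#' @export
print.season_scenario <- function(x, ...) {
  cat(sprintf(
    "Seasonal diving scenario: %d seals x %d days\n  depth %g m -> %g m (days %g-%g) -> %g m; %g dives/day; seed %d\n",
    x$n_seals, x$days, x$deep_depth_early, x$shallow_depth,
    x$shallow_start_day, x$shallow_start_day + x$shallow_duration,
    x$deep_depth_late, x$dives_per_day, x$seed))
  invisible(x)
}

# Days of ramp spent at or below the shallow threshold on the way down and
# up; these are part of the shallowing period, so the flat plateau is the
# requested shallow_duration minus both.
ramp_below <- function(scenario) {
  thr <- scenario$shallow_threshold_m
  r <- scenario$ramp_days
  down <- if (scenario$deep_depth_early <= thr) r else
    r * (thr - scenario$shallow_depth) /
      (scenario$deep_depth_early - scenario$shallow_depth)
  up <- if (scenario$deep_depth_late <= thr) r else
    r * (thr - scenario$shallow_depth) /
      (scenario$deep_depth_late - scenario$shallow_depth)
  c(down = down, up = up)
}

plateau_length <- function(scenario) {
  scenario$shallow_duration - sum(ramp_below(scenario))
}

#' True shallowing period implied by a scenario
#'
#' The exact span over which the noiseless trajectory is at or below the
#' scenario's shallow threshold, for scoring estimates against truth.
#'
#' @param scenario a [season_scenario()].
#' @return list with `start`, `end`, `duration`, `center` (days).
#' @export
shallow_period_truth <- function(scenario) {
  rb <- ramp_below(scenario)
  start <- scenario$shallow_start_day - rb[["down"]]
  end <- start + scenario$shallow_duration
  list(start = start, end = end, duration = scenario$shallow_duration,
       center = (start + end) / 2)
}

#' Deterministic seasonal depth trajectory
#'
#' The noiseless population-mean maximum dive depth on each day of the
#' season: constant at the early-summer depth, a linear ramp into the
#' shallow plateau, the plateau itself, and a linear ramp back out to the
#' late-summer depth. The plateau length is derived from the scenario's
#' `shallow_duration` so that the trajectory spends exactly that many days
#' at or below `shallow_threshold_m` (see [shallow_period_truth()]).
#'
#' @param scenario a [season_scenario()].
#' @param day numeric vector of day-of-season values.
#' @return numeric vector of mean depths (m).
#' @export
depth_trajectory <- function(scenario, day = seq_len(scenario$days)) {
  s0 <- scenario$shallow_start_day
  s1 <- s0 + plateau_length(scenario)
  r  <- scenario$ramp_days
  d  <- numeric(length(day))
  d[day < s0 - r] <- scenario$deep_depth_early
  i <- day >= s0 - r & day < s0
  d[i] <- scenario$deep_depth_early +
    (scenario$shallow_depth - scenario$deep_depth_early) * (day[i] - (s0 - r)) / r
  i <- day >= s0 & day <= s1
  d[i] <- scenario$shallow_depth
  i <- day > s1 & day <= s1 + r
  d[i] <- scenario$shallow_depth +
    (scenario$deep_depth_late - scenario$shallow_depth) * (day[i] - s1) / r
  d[day > s1 + r] <- scenario$deep_depth_late
  d
}

# Build the on-grid depth samples for one trapezoidal dive.
# Returns the per-sample depths at 6 s spacing, starting one sample after the
# dive leaves the surface and ending at the terminal surface sample (depth 0).
# Wiggles are symmetric upward excursions of amplitude `wiggle_amp` planted
# in the flat bottom segment; the amplitude scales with dive depth (~8% of
# max depth, >= 2 m) so that wiggly bottoms are measurably less flat than a
# benthic bottom at any depth, as prey-chase excursions are in real records.
dive_profile <- function(max_depth, n_flat, n_wiggles, dt = 6, rate = 1,
                         wiggle_amp = max(2, round(0.08 * max_depth))) {
  nd <- ceiling(max_depth / (rate * dt))
  desc <- pmin(seq_len(nd) * dt * rate, max_depth)
  flat <- rep(max_depth, n_flat)
  if (n_wiggles > 0) {
    if (n_wiggles > max_wiggles(n_flat))
      stop("flat segment too short for the requested wiggle count")
    a <- wiggle_amp
    w <- c(rep(c(max_depth - a / 2, max_depth - a), n_wiggles),
           max_depth - a / 2)
    flat[2:(1 + length(w))] <- w
  }
  asc <- rev(desc)[-1]
  c(desc, flat, asc, 0)
}

# Maximum number of plantable wiggles in a flat segment of n_flat samples
# (the excursion train takes 2 samples per wiggle plus one closing sample,
# with an untouched flat sample at each end).
max_wiggles <- function(n_flat) pmax(0L, (n_flat - 3L) %/% 2L)

#' Generate synthetic time-depth-recorder data with ground truth
#'
#' Simulates per-seal depth series sampled every 6 s at 0.5 m resolution,
#' composed of trapezoidal ("square-U") dives with constant 1 m/s descent and
#' ascent. Daily mean maximum depth follows [depth_trajectory()] plus Gaussian
#' seal-level and day-level noise; wiggles are planted in the flat bottom
#' segment so that the expected wiggle rate per minute of bottom time equals
#' `wiggle_intercept + wiggle_slope * max_depth`. A small fraction of dives
#' are flat-bottomed benthic dives to a stable seal-specific seabed depth.
#' Every dive carries a machine-readable truth record (max depth, bottom
#' interval, wiggle count, benthic flag), so downstream detectors can be
#' scored without re-deriving truth.
#'
#' @param scenario a [season_scenario()].
#' @param signal logical; if `TRUE` (default) assemble the full 6 s depth
#'   series per seal, otherwise return ground truth only (identical RNG
#'   stream, so truth matches a `signal = TRUE` run with the same seed).
#' @return A list of class `tdr_sim` with elements `records` (data.frame
#'   `seal_id`, `time` seconds since the start of day 1, `depth_m`; `NULL`
#'   when `signal = FALSE`), `truth` (per-dive data.frame), `sealdays`
#'   (truth aggregated per seal-day, benthic dives excluded) and `scenario`.
#' @export
generate_tdr <- function(scenario, signal = TRUE) {
  stopifnot(inherits(scenario, "season_scenario"))
  set.seed(scenario$seed)
  dt <- 6
  day_s <- 86400
  traj <- depth_trajectory(scenario)
  seals <- sprintf("seal%02d", seq_len(scenario$n_seals))
  seal_int <- stats::rnorm(scenario$n_seals, 0, scenario$seal_sd)
  seabed <- quantize_depth(scenario$benthic_depth +
                             stats::rnorm(scenario$n_seals, 0, 10))

  truth_list <- vector("list", scenario$n_seals)
  rec_list <- if (signal) vector("list", scenario$n_seals) else NULL

  for (s in seq_len(scenario$n_seals)) {
    rows <- vector("list", scenario$days)
    sig_t <- list(); sig_d <- list(); si <- 0L
    for (d in seq_len(scenario$days)) {
      day_mean <- traj[d] + seal_int[s] + stats::rnorm(1, 0, scenario$day_sd)
      n_dives <- stats::rpois(1, scenario$dives_per_day)
      if (n_dives == 0L) next
      gap <- round(stats::runif(n_dives, 60, 300) / dt) * dt
      benthic <- stats::runif(n_dives) < scenario$benthic_prob
      D <- quantize_depth(pmax(15, day_mean +
                                 stats::rnorm(n_dives, 0, scenario$dive_sd)))
      D[benthic] <- seabed[s]
      u <- stats::runif(n_dives, 0.3, 0.6)       # flat fraction of duration
      n_flat <- pmax(2L, as.integer(round(u / (1 - u) * 2 * D / dt)))
      # expected wiggle rate per minute of true bottom time (>= 80% span)
      bottom_s_approx <- n_flat * dt + 2 * 0.2 * D
      rate <- pmax(0, scenario$wiggle_intercept + scenario$wiggle_slope * D)
      n_w <- stats::rpois(n_dives, rate * bottom_s_approx / 60)
      n_w[benthic] <- 0L
      # never truncate the planted count: extend the flat segment instead,
      # and draw additional wiggles for the added bottom time, so realized
      # wiggle rates stay unbiased at every depth (truncation or plain
      # extension would deflate rates, mostly on short shallow dives)
      idx <- which(n_w > max_wiggles(n_flat))
      while (length(idx)) {
        n_flat2 <- 2L * n_w[idx] + 3L
        extra <- stats::rpois(length(idx),
                              rate[idx] * (n_flat2 - n_flat[idx]) * dt / 60)
        n_flat[idx] <- n_flat2
        n_w[idx] <- n_w[idx] + extra
        idx <- idx[extra > 0L]
      }
      nd_samp <- ceiling(D / dt)                 # descent samples (1 m/s)
      T_dive <- (2L * nd_samp + n_flat) * dt
      ends <- (d - 1) * day_s + cumsum(gap + T_dive)
      keep <- ends <= d * day_s                  # monotone: a prefix
      if (!any(keep)) next
      ends <- ends[keep]; T_dive <- T_dive[keep]; t0 <- ends - T_dive
      D <- D[keep]; n_flat <- n_flat[keep]; n_w <- n_w[keep]
      nd_samp <- nd_samp[keep]; benthic <- benthic[keep]
      # closed-form truth bottom interval: descent sample j is at depth
      # min(j*dt, D), so the first >= 0.8 D sample is j = ceiling(0.8 D/dt);
      # every flat sample qualifies (wiggle amplitude <= 0.2 D); the ascent
      # mirrors the descent
      j_first <- ceiling(0.8 * D / dt)
      idx_last <- nd_samp + n_flat + pmax(0L, nd_samp - j_first)
      rows[[d]] <- list(day = rep(d, length(t0)), start = t0, end = ends,
                        max_depth = D, duration = T_dive,
                        bottom_start = t0 + j_first * dt,
                        bottom_end = t0 + idx_last * dt,
                        n_wiggles = n_w, benthic = benthic)
      if (signal) {
        for (k in seq_along(t0)) {
          prof <- dive_profile(D[k], n_flat[k], n_w[k], dt = dt)
          si <- si + 1L
          sig_t[[si]] <- t0[k] + seq_along(prof) * dt
          sig_d[[si]] <- prof
        }
      }
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    col <- function(nm) unlist(lapply(rows, `[[`, nm), use.names = FALSE)
    tr <- data.frame(seal_id = seals[s], day = col("day"),
                     start = col("start"), end = col("end"),
                     max_depth = col("max_depth"),
                     duration = col("duration"),
                     bottom_start = col("bottom_start"),
                     bottom_end = col("bottom_end"),
                     n_wiggles = col("n_wiggles"),
                     benthic = col("benthic"), stringsAsFactors = FALSE)
    truth_list[[s]] <- tr
    if (signal) {
      tt <- unlist(sig_t); dd <- unlist(sig_d)
      full_t <- seq(0, scenario$days * day_s, by = dt)
      full_d <- numeric(length(full_t))
      full_d[match(tt, full_t)] <- dd
      rec_list[[s]] <- data.frame(seal_id = seals[s], time = full_t,
                                  depth_m = full_d, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_list)
  truth$bottom_duration <- truth$bottom_end - truth$bottom_start
  truth$date <- scenario$start_date + truth$day - 1L
  out <- list(
    records = if (signal) do.call(rbind, rec_list) else NULL,
    truth = truth,
    sealdays = truth_sealdays(truth),
    scenario = scenario)
  class(out) <- "tdr_sim"
  out
}

# Aggregate per-dive truth into per-seal-day summaries (benthic excluded),
# mirroring what daily_summaries() computes from detected dives.
truth_sealdays <- function(truth) {
  p <- truth[!truth$benthic, , drop = FALSE]
  key <- interaction(p$seal_id, p$day, drop = TRUE)
  agg <- function(f, x) as.numeric(tapply(x, key, f))
  first <- function(x) tapply(as.character(x), key, `[`, 1L)
  data.frame(
    seal_id = as.character(first(p$seal_id)),
    day = as.numeric(tapply(p$day, key, `[`, 1L)),
    date = as.Date(as.character(first(as.character(p$date)))),
    mean_max_depth = agg(mean, p$max_depth),
    n_dives = as.numeric(tapply(p$max_depth, key, length)),
    wiggle_rate = as.numeric(tapply(p$n_wiggles, key, sum) /
                               (tapply(p$bottom_duration, key, sum) / 60)),
    efficiency = agg(mean, p$bottom_duration / p$duration),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.tdr_sim <- function(x, ...) {
  cat(sprintf("Synthetic TDR deployment: %d seals, %d dive truth records%s\n",
              x$scenario$n_seals, nrow(x$truth),
              if (is.null(x$records)) " (truth only)" else
                sprintf(", %d depth samples", nrow(x$records))))
  invisible(x)
}

#' Generate synthetic jaw accelerometry with planted prey-capture bursts
#'
#' Produces a two-axis 20 Hz surge/heave series spanning a set of dives.
#' The background is low-amplitude swimming oscillation (0.8 Hz, ~0.05 g)
#' over a slow swell, which a 1 Hz high-pass leaves well below 0.1 g.
#' At each ground-truth capture time a 4 Hz damped-sinusoid burst with peak
#' 0.4-0.7 g is superimposed, so filtered peaks exceed the 0.3 g detection
#' threshold. Capture times are drawn within dive bottom phases at the
#' requested rate and spaced at least 2 s apart.
#'
#' @param dives data.frame of dive truth records (needs `start`, `end`,
#'   `bottom_start`, `bottom_end`, and `n_wiggles` when
#'   `wiggle_coupling > 0`; as produced by [generate_tdr()]).
#' @param capture_rate expected capture events per minute of bottom time
#'   (>= 0), independent of wiggles.
#' @param wiggle_coupling probability that each planted wiggle is
#'   accompanied by a capture burst (captures cause wiggles); 0 by default,
#'   so `capture_rate = 0` means a burst-free record.
#' @param hz sampling rate (Hz).
#' @param seed integer seed.
#' @return list with `records` (data.frame `time`, `surge_g`, `heave_g`) and
#'   `events` (data.frame of true capture times, one row per planted burst).
#' @export
generate_accel <- function(dives, capture_rate = 0.5, wiggle_coupling = 0,
                           hz = 20, seed = 1L) {
  if (capture_rate < 0) stop("capture_rate must be >= 0")
  if (wiggle_coupling < 0 || wiggle_coupling > 1)
    stop("wiggle_coupling must be in [0, 1]")
  stopifnot(nrow(dives) >= 1)
  set.seed(seed)
  t0 <- min(dives$start) - 60
  t1 <- max(dives$end) + 60
  t <- seq(t0, t1, by = 1 / hz)
  n <- length(t)
  phase <- stats::runif(2, 0, 2 * pi)
  surge <- 0.05 * sin(2 * pi * 0.8 * t + phase[1]) +
    0.08 * sin(2 * pi * 0.05 * t + phase[2]) +
    stats::rnorm(n, 0, 0.01)
  heave <- 0.05 * cos(2 * pi * 0.8 * t + phase[1]) + stats::rnorm(n, 0, 0.01)

  ev <- list(); ei <- 0L
  for (i in seq_len(nrow(dives))) {
    bs <- dives$bottom_start[i]; be <- dives$bottom_end[i]
    bmin <- (be - bs) / 60
    if (bmin <= 0) next
    n_ev <- stats::rpois(1, capture_rate * bmin)
    if (wiggle_coupling > 0 && "n_wiggles" %in% names(dives))
      n_ev <- n_ev + stats::rbinom(1, dives$n_wiggles[i], wiggle_coupling)
    if (n_ev == 0L) next
    slots <- seq(bs + 1, be - 1, by = 2)        # >= 2 s apart by construction
    n_ev <- min(n_ev, length(slots))
    times <- sort(sample(slots, n_ev))
    for (tm in times) {
      ei <- ei + 1L
      amp <- stats::runif(1, 0.4, 0.7)
      ev[[ei]] <- data.frame(time = tm, amp = amp,
                             dive_row = i, stringsAsFactors = FALSE)
      idx <- which(t >= tm & t < tm + 0.5)
      tb <- t[idx] - tm
      surge[idx] <- surge[idx] + amp * exp(-tb / 0.1) * sin(2 * pi * 4 * tb + pi / 2)
      heave[idx] <- heave[idx] + 0.3 * amp * exp(-tb / 0.1) * sin(2 * pi * 4 * tb)
    }
  }
  events <- if (ei) do.call(rbind, ev) else
    data.frame(time = numeric(0), amp = numeric(0), dive_row = integer(0))
  list(records = data.frame(time = t, surge_g = surge, heave_g = heave),
       events = events)
}
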