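#' Generate a synthetic daily sea-ice concentration grid
#'
#' Builds a long-format daily ice-concentration table for a set of grid cells.
#' Each cell starts above 80% cover and, three days before its requested
#' break-out day, steps down to low cover with bounded day-to-day noise, so
#' that the trailing 7-day running mean first drops below 50% exactly on the
#' requested day (the construction keeps a >4% margin on both sides of the
#' threshold, and the uniform noise has mean amplitude below that margin).
#' Cells with `NA` break-out day never decline. An optional transient
#' refreeze raises cover back to ~70% for ten days starting 15 days after
#' break-out; the first-occurrence break-out date is unaffected.
#'
#' @param breakout_days named numeric vector of requested break-out days
#'   (index into the series, 1-based), names matching `cells$name`; `NA`
#'   means no break-out.
#' @param n_days length of the daily series.
#' @param start_date calendar date of day 1.
#' @param cells data.frame with columns `name`, `lat`, `lon`
#'   (default [ross_island_sources()]).
#' @param refreeze logical; add a transient refreeze episode after break-out.
#' @param seed integer seed.
#' @return data.frame of class `ice_grid` with columns `date`, `cell_id`,
#'   `lat`, `lon`, `concentration_pct`.
#' @export
generate_ice <- function(breakout_days, n_days = 120,
                         start_date = as.Date("2016-10-01"),
                         cells = ross_island_sources(),
                         refreeze = FALSE, seed = 1L) {
  if (is.null(names(breakout_days)) ||
      !all(names(breakout_days) %in% cells$name))
    stop("breakout_days must be named after cells")
  ok <- !is.na(breakout_days)
  if (any(breakout_days[ok] < 8 | breakout_days[ok] > n_days))
    stop("breakout days must lie within the simulated calendar (>= 8)")
  set.seed(seed)
  dates <- start_date + seq_len(n_days) - 1L
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    b <- breakout_days[cells$name[i]]
    conc <- 88 + stats::runif(n_days, -3, 3)
    if (!is.na(b)) {
      drop_day <- b - 3L
      conc[drop_day:n_days] <- 18 + stats::runif(n_days - drop_day + 1, -3, 3)
      if (refreeze) {
        rf <- (b + 15L):min(b + 24L, n_days)
        if (length(rf)) conc[rf] <- 70 + stats::runif(length(rf), -3, 3)
      }
    }
    out[[i]] <- data.frame(date = dates, cell_id = cells$name[i],
                           lat = cells$lat[i], lon = cells$lon[i],
                           concentration_pct = pmin(100, pmax(0, conc)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("ice_grid", "data.frame")
  res
}

#' Synthetic prey-source isotope table
#'
#' A five-group prey source table (means, SDs and trophic enrichment factors
#' for both isotopes) constructed for this package's simulations and examples.
#' It is a synthetic stand-in patterned on the Ross Sea prey community — a
#' silverfish-dominated group, a *Pagothenia borchgrevinki* / *Trematomus*
#' group, and three minor groups — with TEF-corrected means placed so that a
#' diet of roughly (0.72, 0.20, 0.04, 0.02, 0.02) yields a consumer signature
#' near delta-15N 13.0 permil and delta-13C -23.2 permil. It is not a
#' published prey dataset.
#'
#' @return data.frame with columns `name`, `mean_d15N`, `sd_d15N`,
#'   `mean_d13C`, `sd_d13C`, `tef_d15N_mean`, `tef_d15N_sd`,
#'   `tef_d13C_mean`, `tef_d13C_sd`.
#' @export
synthetic_prey_sources <- function() {
  data.frame(
    name = c("silverfish_group", "borchgrevinki_trematomus",
             "myctophid_group", "benthic_fish_group", "crustacean_group"),
    mean_d15N = c(9.72, 11.4, 7.5, 12.5, 8.5),
    sd_d15N = 0.5,
    mean_d13C = c(-24.6, -23.0, -26.0, -21.5, -22.0),
    sd_d13C = 0.3,
    tef_d15N_mean = 3.0, tef_d15N_sd = 0.5,
    tef_d13C_mean = 1.0, tef_d13C_sd = 0.3,
    stringsAsFactors = FALSE)
}

#' Generate synthetic whisker isotope series
#'
#' Draws per-seal consumer isotope values from the mixing model's own
#' likelihood given a source table and a true diet-proportion vector: each
#' seal mean is Normal with mean `sum(p * (source + TEF))` and variance
#' `sum(p^2 * (source SD^2 + TEF SD^2)) + sigma^2` per isotope. Whisker
#' segments then scatter around the seal mean with an optional linear
#' temporal trend (default none, matching a diet that does not shift over
#' the season).
#'
#' @param n_seals number of seals.
#' @param n_segments whisker segments per seal.
#' @param trend temporal trend in permil per day applied to both isotopes.
#' @param sources source table as from [synthetic_prey_sources()].
#' @param true_p true diet proportions (must sum to 1 within 1e-9).
#' @param sigma process SDs, one per isotope, `c(d15N, d13C)`.
#' @param segment_sd within-seal segment scatter (permil).
#' @param deploy_date,recover_date deployment window used to date segments.
#' @param seed integer seed.
#' @return list with `whiskers` (seal_id, segment, date, d15N, d13C),
#'   `consumers` (per-seal mean values), `sources`, `true_p`.
#' @export
generate_isotopes <- function(n_seals = 9, n_segments = 5, trend = 0,
                              sources = synthetic_prey_sources(),
                              true_p = c(0.72, 0.20, 0.04, 0.02, 0.02),
                              sigma = c(0.15, 0.10), segment_sd = 0.15,
                              deploy_date = as.Date("2013-11-15"),
                              recover_date = as.Date("2014-01-15"),
                              seed = 1L) {
  if (abs(sum(true_p) - 1) > 1e-9)
    stop("true_p must sum to 1 (tolerance 1e-9)")
  if (length(true_p) != nrow(sources))
    stop("true_p length must match the number of sources")
  set.seed(seed)
  mu <- cbind(sources$mean_d15N + sources$tef_d15N_mean,
              sources$mean_d13C + sources$tef_d13C_mean)
  vv <- cbind(sources$sd_d15N^2 + sources$tef_d15N_sd^2,
              sources$sd_d13C^2 + sources$tef_d13C_sd^2)
  m <- as.numeric(true_p %*% mu)
  v <- as.numeric((true_p^2) %*% vv) + sigma^2
  seal_means <- cbind(stats::rnorm(n_seals, m[1], sqrt(v[1])),
                      stats::rnorm(n_seals, m[2], sqrt(v[2])))
  seals <- sprintf("seal%02d", seq_len(n_seals))
  dates <- assign_segment_dates(n_segments, deploy_date, recover_date)
  rows <- vector("list", n_seals)
  mid <- mean(as.numeric(dates$date))
  for (s in seq_len(n_seals)) {
    dd <- as.numeric(dates$date) - mid
    rows[[s]] <- data.frame(
      seal_id = seals[s], segment = dates$segment, date = dates$date,
      d15N = seal_means[s, 1] + trend * dd +
        stats::rnorm(n_segments, 0, segment_sd),
      d13C = seal_means[s, 2] + trend * dd +
        stats::rnorm(n_segments, 0, segment_sd),
      stringsAsFactors = FALSE)
  }
  list(whiskers = do.call(rbind, rows),
       consumers = data.frame(seal_id = seals, d15N = seal_means[, 1],
                              d13C = seal_means[, 2],
                              stringsAsFactors = FALSE),
       sources = sources, true_p = true_p)
}
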