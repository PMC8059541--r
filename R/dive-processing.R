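#' Zero-offset correction for a depth record
#'
#' Removes slow pressure-sensor drift so that surface intervals read ~0 m.
#' The offset is estimated as the rolling 10th percentile of shallow readings
#' (below `shallow_cut`) within consecutive 2-hour windows, linearly
#' interpolated across window centres, subtracted from every sample, and the
#' result clamped at 0 m.
#'
#' @param record data.frame with columns `time` (seconds, strictly
#'   increasing) and `depth_m`.
#' @param window_s offset-estimation window (s).
#' @param shallow_cut only readings shallower than this (m) inform the
#'   offset.
#' @return the record with `depth_m` corrected.
#' @export
zero_offset_correct <- function(record, window_s = 7200, shallow_cut = 15) {
  stopifnot(nrow(record) > 0)
  d <- record$depth_m
  blk <- floor((record$time - record$time[1]) / window_s)
  centres <- tapply(record$time, blk, mean)
  offs <- tapply(seq_along(d), blk, function(i) {
    s <- d[i][d[i] < shallow_cut]
    if (length(s) == 0) NA_real_ else stats::quantile(s, 0.1, names = FALSE)
  })
  if (all(is.na(offs))) {
    warning("no surface samples found; zero-offset correction skipped")
    return(record)
  }
  if (sum(!is.na(offs)) == 1L) {
    off <- rep(offs[!is.na(offs)], nrow(record))
  } else {
    off <- stats::approx(as.numeric(centres)[!is.na(offs)],
                         offs[!is.na(offs)], xout = record$time,
                         rule = 2)$y
  }
  record$depth_m <- pmax(0, d - off)
  record
}

#' Detect dives in a corrected depth record
#'
#' A dive is a maximal contiguous excursion below the surface threshold that
#' reaches at least `min_depth` and lasts at least `min_duration`. Dive start
#' and end are placed at the last surface sample before and the first surface
#' sample after the excursion. Sampling gaps longer than twice the nominal
#' interval break the record: no dive spans an instrument dropout.
#'
#' @param record corrected depth record (`time`, `depth_m`, optional
#'   `seal_id`).
#' @param min_depth minimum maximum-depth to qualify as a dive (m).
#' @param min_duration minimum dive duration (s).
#' @param surface_threshold depth above which a sample counts as "at the
#'   surface" (m).
#' @return data.frame with one row per dive: `dive_id`, `seal_id`, `start`,
#'   `end`, `duration`, `max_depth`, `start_idx`, `end_idx` (indices into
#'   `record`). Zero rows if no dives.
#' @export
detect_dives <- function(record, min_depth = 10, min_duration = 30,
                         surface_threshold = 2) {
  n <- nrow(record)
  empty <- data.frame(dive_id = integer(0), seal_id = character(0),
                      start = numeric(0), end = numeric(0),
                      duration = numeric(0), max_depth = numeric(0),
                      start_idx = integer(0), end_idx = integer(0),
                      stringsAsFactors = FALSE)
  if (n < 3) return(empty)
  tm <- record$time
  dts <- diff(tm)
  dt_nom <- stats::median(dts)
  seg <- cumsum(c(0, dts > 2 * dt_nom))        # contiguous segments
  wet <- record$depth_m > surface_threshold
  code <- paste0(seg, "_", wet)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iswet <- grepl("_TRUE$", r$values)
  out <- list(); k <- 0L
  for (j in which(iswet)) {
    i0 <- starts[j]; i1 <- ends[j]
    # extend to adjacent surface samples within the same segment
    s0 <- if (i0 > 1 && seg[i0 - 1] == seg[i0]) i0 - 1L else i0
    s1 <- if (i1 < n && seg[i1 + 1] == seg[i1]) i1 + 1L else i1
    md <- max(record$depth_m[i0:i1])
    dur <- tm[s1] - tm[s0]
    if (md >= min_depth && dur >= min_duration) {
      k <- k + 1L
      out[[k]] <- data.frame(
        dive_id = k,
        seal_id = if ("seal_id" %in% names(record))
          record$seal_id[i0] else NA_character_,
        start = tm[s0], end = tm[s1], duration = dur, max_depth = md,
        start_idx = s0, end_idx = s1, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  do.call(rbind, out)
}

#' Bottom phase of a dive
#'
#' The bottom phase spans the first to the last sample whose depth is at
#' least `fraction` (default 80%) of the dive's maximum depth.
#'
#' @param times,depths the dive's samples.
#' @param fraction bottom-phase depth fraction of maximum depth.
#' @return list with `bottom_start`, `bottom_end`, `bottom_duration` (s).
#' @export
compute_bottom_phase <- function(times, depths, fraction = 0.8) {
  stopifnot(length(times) >= 3, length(times) == length(depths))
  thr <- fraction * max(depths)
  idx <- which(depths >= thr)
  list(bottom_start = times[idx[1]],
       bottom_end = times[idx[length(idx)]],
       bottom_duration = times[idx[length(idx)]] - times[idx[1]])
}

#' Count bottom-phase wiggles
#'
#' A wiggle is a vertical direction reversal — a shallowing excursion of at
#' least `min_excursion` that is followed by a deepening of at least
#' `min_excursion` — within the supplied (bottom-phase) depth samples. A
#' monotone traverse counts zero; depth-quantization chatter of half the
#' threshold or less never counts.
#'
#' @param depths bottom-phase depth samples (m).
#' @param min_excursion minimum limb amplitude (m) on both sides of the
#'   reversal.
#' @return integer wiggle count.
#' @export
count_wiggles <- function(depths, min_excursion = 1.0) {
  n <- length(depths)
  if (n < 3) return(0L)
  count <- 0L
  ref_high <- depths[1]
  armed <- FALSE
  cur_min <- Inf
  for (v in depths[-1]) {
    if (!armed) {
      if (v > ref_high) ref_high <- v
      if (ref_high - v >= min_excursion) {
        armed <- TRUE
        cur_min <- v
      }
    } else {
      if (v < cur_min) cur_min <- v
      if (v - cur_min >= min_excursion) {
        count <- count + 1L
        armed <- FALSE
        ref_high <- v
      }
    }
  }
  count
}

#' Fill per-dive metrics
#'
#' Computes, for each detected dive, the bottom phase, its duration, the
#' wiggle count and the coefficient of variation of bottom-phase depths
#' (used by the benthic classifier).
#'
#' @param record the corrected depth record the dives were detected in.
#' @param dives output of [detect_dives()].
#' @param params an [ip_params()] object.
#' @return `dives` with columns `bottom_start`, `bottom_end`,
#'   `bottom_duration`, `n_wiggles`, `bottom_cv`, `efficiency` added.
#' @export
dive_metrics <- function(record, dives, params = ip_params()) {
  n <- nrow(dives)
  bs <- be <- bd <- cvv <- numeric(n)
  nw <- integer(n)
  for (i in seq_len(n)) {
    idx <- dives$start_idx[i]:dives$end_idx[i]
    tt <- record$time[idx]; dd <- record$depth_m[idx]
    bp <- compute_bottom_phase(tt, dd, params$bottom_fraction)
    bs[i] <- bp$bottom_start; be[i] <- bp$bottom_end
    bd[i] <- bp$bottom_duration
    bidx <- which(tt >= bp$bottom_start & tt <= bp$bottom_end)
    nw[i] <- count_wiggles(dd[bidx], params$wiggle_min_excursion_m)
    # flatness of the central 60% of the bottom phase: trimming the
    # shoulders of the 80% envelope keeps the CV a measure of how flat the
    # bottom itself is, not of the descent/ascent limbs crossing it
    nb <- length(bidx)
    trim <- if (nb >= 5) floor(0.2 * nb) else 0L
    core <- dd[bidx][(1L + trim):(nb - trim)]
    cvv[i] <- cv(core)
  }
  dives$bottom_start <- bs
  dives$bottom_end <- be
  dives$bottom_duration <- bd
  dives$n_wiggles <- nw
  dives$bottom_cv <- cvv
  dives$efficiency <- ifelse(dives$duration > 0, bd / dives$duration, 0)
  dives
}

#' Classify dives as benthic or pelagic
#'
#' A dive is benthic when its maximum depth reaches at least
#' `benthic_depth_ratio` (default 0.9) of the seal's rolling 7-day maximum
#' dive depth and its bottom-phase depth coefficient of variation is at most
#' `benthic_cv_max` (default 0.02) — i.e., a flat bottom at the local depth
#' ceiling. Dives with less than one day of prior history for that seal are
#' classified pelagic and flagged (`history_ok = FALSE`).
#'
#' @param dives dive table with metrics filled (needs `seal_id`, `day` or
#'   `start` to derive days, `max_depth`, `bottom_cv`).
#' @param params an [ip_params()] object.
#' @return `dives` with `dive_class` (`"benthic"`/`"pelagic"`) and
#'   `history_ok` added.
#' @export
classify_dives <- function(dives, params = ip_params()) {
  if (!"day" %in% names(dives))
    dives$day <- floor(dives$start / 86400) + 1L
  dives$dive_class <- "pelagic"
  dives$history_ok <- TRUE
  w <- params$benthic_window_days
  for (s in unique(dives$seal_id)) {
    i <- which(dives$seal_id == s)
    dsub <- dives[i, ]
    day0 <- min(dsub$day)
    days <- sort(unique(dsub$day))
    daymax <- tapply(dsub$max_depth, factor(dsub$day, levels = days), max)
    rollmax <- vapply(days, function(d)
      max(daymax[days >= d - (w - 1L) & days <= d]), numeric(1))
    names(rollmax) <- days
    rm_i <- rollmax[as.character(dsub$day)]
    benthic <- dsub$max_depth >= params$benthic_depth_ratio * rm_i &
      dsub$bottom_cv <= params$benthic_cv_max
    hist_ok <- dsub$day - day0 >= 1
    benthic[!hist_ok] <- FALSE
    dives$dive_class[i][benthic] <- "benthic"
    dives$history_ok[i] <- hist_ok
  }
  dives
}

#' Seasonal trend in benthic dive depths
#'
#' Random-intercept linear model of benthic maximum dive depth on day of
#' season (one intercept per seal), testing whether benthic depths drift
#' across the summer.
#'
#' @param benthic_dives dive table restricted to benthic dives (needs
#'   `seal_id`, `day`, `max_depth`).
#' @param level confidence level for the Wald interval.
#' @return list with `slope` (m/day), `se`, `ci`, `covers_zero`, `n`.
#' @export
benthic_depth_trend <- function(benthic_dives, level = 0.95) {
  if (length(unique(benthic_dives$seal_id)) < 2)
    stop("need at least 2 seals")
  if (nrow(benthic_dives) < 10)
    stop("need at least 10 benthic dives")
  if (length(unique(benthic_dives$day)) < 2)
    stop("degenerate design: a single date")
  fit <- lme4::lmer(max_depth ~ day + (1 | seal_id), data = benthic_dives)
  co <- summary(fit)$coefficients
  slope <- co["day", "Estimate"]; se <- co["day", "Std. Error"]
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- slope + c(-1, 1) * z * se
  list(slope = slope, se = se, ci = ci,
       covers_zero = ci[1] <= 0 && ci[2] >= 0, n = nrow(benthic_dives))
}

#' Per-seal-day and across-seal daily summaries
#'
#' Benthic dives are excluded. Per seal-day: mean maximum dive depth, dive
#' count, wiggle rate (total wiggles per total bottom minutes) and mean
#' diving efficiency (bottom duration / dive duration). The across-seal table
#' averages the seal-day values per calendar day, weighting each seal-day
#' equally.
#'
#' @param dives classified dive table.
#' @return list with `sealdays` and `daily` data.frames.
#' @export
daily_summaries <- function(dives) {
  p <- dives[dives$dive_class != "benthic", , drop = FALSE]
  if (!"day" %in% names(p)) p$day <- floor(p$start / 86400) + 1L
  key <- interaction(p$seal_id, p$day, drop = TRUE)
  sealdays <- data.frame(
    seal_id = as.character(tapply(as.character(p$seal_id), key, `[`, 1L)),
    day = as.numeric(tapply(p$day, key, `[`, 1L)),
    mean_max_depth = as.numeric(tapply(p$max_depth, key, mean)),
    n_dives = as.numeric(tapply(p$max_depth, key, length)),
    wiggle_rate = as.numeric(tapply(p$n_wiggles, key, sum) /
                               (tapply(p$bottom_duration, key, sum) / 60)),
    efficiency = as.numeric(tapply(p$bottom_duration / p$duration,
                                   key, mean)),
    row.names = NULL, stringsAsFactors = FALSE)
  if ("date" %in% names(p))
    sealdays$date <- as.Date(
      as.character(tapply(as.character(p$date), key, `[`, 1L)))
  dk <- factor(sealdays$day)
  daily <- data.frame(
    day = as.numeric(levels(dk)),
    mean_max_depth = as.numeric(tapply(sealdays$mean_max_depth, dk, mean)),
    wiggle_rate = as.numeric(tapply(sealdays$wiggle_rate, dk, mean)),
    efficiency = as.numeric(tapply(sealdays$efficiency, dk, mean)),
    n_seals = as.numeric(tapply(sealdays$seal_id, dk,
                                function(x) length(unique(x)))),
    row.names = NULL, stringsAsFactors = FALSE)
  list(sealdays = sealdays, daily = daily)
}

#' Process a raw depth record end to end
#'
#' Convenience wrapper: zero-offset correction, dive detection, per-dive
#' metrics and benthic/pelagic classification, per seal.
#'
#' @param records depth records for one or more seals (`seal_id`, `time`,
#'   `depth_m`).
#' @param params an [ip_params()] object.
#' @return classified dive table for all seals.
#' @export
process_tdr <- function(records, params = ip_params()) {
  out <- lapply(split(records, records$seal_id), function(rec) {
    rec <- zero_offset_correct(rec)
    dv <- detect_dives(rec, params$min_dive_depth_m,
                       params$min_dive_duration_s,
                       params$surface_threshold_m)
    if (nrow(dv) == 0) return(NULL)
    dive_metrics(rec, dv, params)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  classify_dives(out, params)
}
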