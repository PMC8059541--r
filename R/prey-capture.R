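#' Zero-phase high-pass filter for surge acceleration
#'
#' Removes gravity, body orientation and slow swimming components from the
#' surge axis with a 4th-order Butterworth high-pass applied forward and
#' backward (zero phase), so that a fixed amplitude threshold on the residual
#' is meaningful for strike transients.
#'
#' @param x surge series (g).
#' @param hz sampling rate (Hz).
#' @param cutoff_hz high-pass cutoff (Hz).
#' @return filtered series, same length as `x`.
#' @export
highpass_surge <- function(x, hz = 20, cutoff_hz = 1.0) {
  n <- length(x)
  if (n < 2 * hz)
    stop("record shorter than filter warm-up (need >= 2 s of data)")
  bf <- signal::butter(4, cutoff_hz / (hz / 2), type = "high")
  # odd-reflection padding suppresses the start/end transients that a plain
  # forward-backward pass leaves on finite records
  L <- min(n - 1, 3 * hz)
  xp <- c(2 * x[1] - x[(L + 1):2], x, 2 * x[n] - x[(n - 1):(n - L)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(L + 1):(L + n)]
}

#' Detect prey-capture attempts in filtered surge acceleration
#'
#' Contiguous excursions of rectified (absolute) filtered surge at or above
#' `threshold_g` are events; excursions separated by less than `refractory_s`
#' are merged into one event, timed at the absolute peak.
#'
#' @param time sample times (s), uniform grid.
#' @param surge filtered surge (g), as from [highpass_surge()].
#' @param threshold_g detection threshold (g), inclusive.
#' @param refractory_s minimum separation between distinct events (s).
#' @return data.frame with one row per event: `time`, `peak_surge`,
#'   `start`, `end`.
#' @export
detect_prey_captures <- function(time, surge, threshold_g = 0.3,
                                 refractory_s = 1.0) {
  stopifnot(length(time) == length(surge))
  a <- abs(surge)
  hot <- a >= threshold_g
  empty <- data.frame(time = numeric(0), peak_surge = numeric(0),
                      start = numeric(0), end = numeric(0))
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs whose gap is below the refractory interval
  merged <- list(); m <- 0L
  cur <- runs[1, ]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (time[runs[i, 1]] - time[cur[2]] < refractory_s) {
      cur[2] <- runs[i, 2]
    } else {
      m <- m + 1L; merged[[m]] <- cur
      cur <- runs[i, ]
    }
  }
  merged[[m + 1L]] <- cur
  out <- lapply(merged, function(rn) {
    idx <- rn[1]:rn[2]
    pk <- idx[which.max(a[idx])]
    data.frame(time = time[pk], peak_surge = a[pk],
               start = time[rn[1]], end = time[rn[2]])
  })
  do.call(rbind, out)
}

#' Jaw-motion rates per dive and per day, and their wiggle correlation
#'
#' Assigns capture events to dives by time containment, computes the
#' per-dive jaw rate (events per minute of bottom time) and per-day rates,
#' and correlates the per-day jaw rate with the per-day wiggle rate — the
#' two feeding proxies.
#'
#' @param events data.frame from [detect_prey_captures()].
#' @param dives dive table with metrics (needs `start`, `end`,
#'   `bottom_duration`, `n_wiggles`, optionally `day`).
#' @return list with `per_dive` (dives plus `n_events`, `jaw_rate`),
#'   `per_day` (day, jaw_rate, wiggle_rate), and `correlation`
#'   (estimate, ci, p) when >= 3 days are available.
#' @export
jaw_rate_per_dive <- function(events, dives) {
  if (nrow(dives) == 0) stop("no dives supplied")
  if (nrow(events) > 0) {
    gap <- max(min(dives$start) - max(events$time),
               min(events$time) - max(dives$end), 0)
    if (gap > 86400)
      stop("no temporal overlap between events and dives")
  }
  n_ev <- vapply(seq_len(nrow(dives)), function(i)
    sum(events$time >= dives$start[i] & events$time <= dives$end[i]),
    numeric(1))
  dives$n_events <- n_ev
  dives$jaw_rate <- ifelse(dives$bottom_duration > 0,
                           n_ev / (dives$bottom_duration / 60), 0)
  if (!"day" %in% names(dives))
    dives$day <- floor(dives$start / 86400) + 1L
  dk <- factor(dives$day)
  per_day <- data.frame(
    day = as.numeric(levels(dk)),
    jaw_rate = as.numeric(tapply(dives$n_events, dk, sum) /
                            (tapply(dives$bottom_duration, dk, sum) / 60)),
    wiggle_rate = as.numeric(tapply(dives$n_wiggles, dk, sum) /
                               (tapply(dives$bottom_duration, dk, sum) / 60)),
    row.names = NULL)
  correlation <- NULL
  if (nrow(per_day) >= 3 &&
      stats::sd(per_day$jaw_rate) > 0 && stats::sd(per_day$wiggle_rate) > 0) {
    ct <- stats::cor.test(per_day$jaw_rate, per_day$wiggle_rate)
    correlation <- list(estimate = unname(ct$estimate),
                        ci = as.numeric(ct$conf.int), p = ct$p.value)
  }
  list(per_dive = dives, per_day = per_day, correlation = correlation)
}
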