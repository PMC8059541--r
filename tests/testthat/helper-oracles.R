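# Independent brute-force oracles. These re-derive each quantity from its
# definition with a deliberately naive algorithm, so that the package
# implementations can be checked exactly on randomized instances.

# Haversine from first principles (no geosphere).
oracle_haversine_km <- function(lat1, lon1, lat2, lon2, R = 6371) {
  to <- pi / 180
  h <- sin((lat2 - lat1) * to / 2)^2 +
    cos(lat1 * to) * cos(lat2 * to) * sin((lon2 - lon1) * to / 2)^2
  2 * R * asin(sqrt(h))
}

# First index whose trailing k-mean is strictly below thr; NA if none.
oracle_breakout_idx <- function(conc, k = 7, thr = 50) {
  for (i in k:length(conc)) {
    if (mean(conc[(i - k + 1):i]) < thr) return(i)
  }
  NA_integer_
}

# Dive scan on a gapless record: walk the samples, extend each wet run to
# its neighbouring surface samples, apply the depth/duration gates.
oracle_detect_dives <- function(time, depth, min_depth = 10,
                                min_duration = 30, surf = 2) {
  n <- length(depth)
  out <- list(); k <- 0L; i <- 1L
  while (i <= n) {
    if (depth[i] > surf) {
      j <- i
      while (j < n && depth[j + 1] > surf) j <- j + 1L
      s <- max(1L, i - 1L); e <- min(n, j + 1L)
      md <- max(depth[i:j])
      if (md >= min_depth && time[e] - time[s] >= min_duration) {
        k <- k + 1L
        out[[k]] <- c(start = time[s], end = time[e], max_depth = md)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (k == 0L) return(NULL)
  do.call(rbind, out)
}

# Bottom phase straight from the definition.
oracle_bottom_phase <- function(time, depth, fraction = 0.8) {
  idx <- which(depth >= fraction * max(depth))
  c(start = time[idx[1]], end = time[idx[length(idx)]])
}

# Wiggle count via repeated full rescans of the running max/min (O(n^2)):
# arm on a shallowing of >= e below the running maximum, count on a
# deepening of >= e above the running minimum since arming, then restart
# from the counting sample.
oracle_count_wiggles <- function(d, e = 1) {
  count <- 0L; start <- 1L; n <- length(d)
  repeat {
    arm <- NA_integer_
    for (j in start:n) {
      if (max(d[start:j]) - d[j] >= e) { arm <- j; break }
    }
    if (is.na(arm)) return(count)
    done <- NA_integer_
    for (j in arm:n) {
      if (d[j] - min(d[arm:j]) >= e) { done <- j; break }
    }
    if (is.na(done)) return(count)
    count <- count + 1L
    start <- done
  }
}

# Capture events by grouping super-threshold samples whose spacing is below
# the refractory interval; event time at the group's absolute peak.
oracle_detect_captures <- function(time, a, thr = 0.3, refr = 1.0) {
  hot <- which(abs(a) >= thr)
  if (!length(hot)) return(NULL)
  grp <- cumsum(c(1, diff(time[hot]) >= refr))
  t(vapply(split(hot, grp), function(idx) {
    pk <- idx[which.max(abs(a[idx]))]
    c(time = time[pk], peak = abs(a[pk]))
  }, numeric(2)))
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}
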