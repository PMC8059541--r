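# Internal helpers shared across modules.

# Quantize depths to the sensor resolution (default 0.5 m).
quantize_depth <- function(x, resolution = 0.5) {
  round(x / resolution) * resolution
}

# Trailing running mean over `k` observations; NA for the first k-1 positions
# and for any window containing an NA.
trailing_mean <- function(x, k) {
  n <- length(x)
  if (n < k) return(rep(NA_real_, n))
  cs <- cumsum(ifelse(is.na(x), 0, x))
  bad <- cumsum(is.na(x))
  out <- rep(NA_real_, n)
  i <- k:n
  nbad <- bad[i] - c(0, bad)[i - k + 1]
  m <- (cs[i] - c(0, cs)[i - k + 1]) / k
  m[nbad > 0] <- NA_real_
  out[i] <- m
  out
}

# Round half away from zero (so 2.5 -> 3), unlike base round()'s banker's
# rounding; durations in whole days use this.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# stats-style coefficient of variation, 0 for a constant vector.
cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(0)
  stats::sd(x) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
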