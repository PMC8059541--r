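# Small fixtures built in code.

# A trapezoidal dive record on the 6 s grid: descend at 1 m/s, hold,
# ascend; padded with surface samples on both sides.
make_trapezoid_record <- function(max_depth = 120, flat_samples = 10,
                                  pad = 10, dt = 6, seal_id = "s1") {
  nd <- ceiling(max_depth / dt)
  prof <- c(rep(0, pad), pmin(seq_len(nd) * dt, max_depth),
            rep(max_depth, flat_samples),
            rev(pmin(seq_len(nd) * dt, max_depth))[-1], rep(0, pad))
  data.frame(seal_id = seal_id, time = seq_along(prof) * dt - dt,
             depth_m = prof)
}

# A triangular (V-shaped) dive record.
make_triangle_record <- function(max_depth = 120, pad = 10, dt = 6) {
  nd <- ceiling(max_depth / dt)
  prof <- c(rep(0, pad), pmin(seq_len(nd) * dt, max_depth),
            rev(pmin(seq_len(nd) * dt, max_depth))[-1], rep(0, pad))
  data.frame(seal_id = "s1", time = seq_along(prof) * dt - dt,
             depth_m = prof)
}

# A small, fast scenario for signal-level tests.
small_scenario <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_seals = 2, days = 12, dives_per_day = 12, shallow_start_day = 6,
         shallow_duration = 4, ramp_days = 2, seed = seed),
    list(...))
  do.call(season_scenario, args)
}

# Two well-separated sources with zero variance, for closed-form checks.
two_sources_1iso <- function() {
  data.frame(name = c("A", "B"), mean_d15N = c(0, 10), sd_d15N = 0,
             tef_d15N_mean = 0, tef_d15N_sd = 0, stringsAsFactors = FALSE)
}

two_sources_2iso <- function(sd = 1) {
  data.frame(name = c("A", "B"),
             mean_d15N = c(0, 10), sd_d15N = sd,
             mean_d13C = c(0, 10), sd_d13C = sd,
             tef_d15N_mean = 0, tef_d15N_sd = 0,
             tef_d13C_mean = 0, tef_d13C_sd = 0, stringsAsFactors = FALSE)
}

# local 0.5 m quantizer (tests run against the installed package's exports)
quant05 <- function(x) round(x * 2) / 2
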