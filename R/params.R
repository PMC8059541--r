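#' Analysis parameters
#'
#' One configurable home for every named constant used by the pipeline. The
#' defaults are the values used throughout: the bottom phase is the part of a
#' dive at >= 80% of its maximum depth; a prey-capture attempt is a filtered
#' surge-acceleration excursion of at least 0.3 g; sea-ice break-out is the
#' first date whose trailing 7-day mean concentration falls below 50%; the
#' seal shallowing period is the span where the fitted across-seal mean dive
#' depth stays at or below 140 m; the near-surface phytoplankton bloom is
#' taken to last 35 days from advective arrival; and the three candidate
#' current velocities are 6.5, 10.3 and 12 km per day.
#'
#' @param ... name = value overrides for any default listed below.
#'
#' @return An object of class `ip_params`: a named list with elements
#'   `bottom_fraction` (0.8), `capture_threshold_g` (0.3),
#'   `capture_refractory_s` (1), `highpass_cutoff_hz` (1),
#'   `ice_window_days` (7), `ice_threshold_pct` (50),
#'   `shallow_threshold_m` (140), `bloom_days` (35),
#'   `velocities_km_day` (6.5, 10.3, 12), `flank_days` (10),
#'   `surface_threshold_m` (2), `min_dive_depth_m` (10),
#'   `min_dive_duration_s` (30), `wiggle_min_excursion_m` (1),
#'   `benthic_depth_ratio` (0.9), `benthic_cv_max` (0.02),
#'   `benthic_window_days` (7), `sampling_interval_s` (6),
#'   `depth_resolution_m` (0.5), `accel_hz` (20), `basis_dim` (15).
#'
#' @examples
#' p <- ip_params(capture_threshold_g = 0.4)
#' p$capture_threshold_g
#' @export
ip_params <- function(...) {
  p <- list(
    bottom_fraction        = 0.8,
    capture_threshold_g    = 0.3,
    capture_refractory_s   = 1,
    highpass_cutoff_hz     = 1,
    ice_window_days        = 7L,
    ice_threshold_pct      = 50,
    shallow_threshold_m    = 140,
    bloom_days             = 35L,
    velocities_km_day      = c(6.5, 10.3, 12),
    flank_days             = 10L,
    surface_threshold_m    = 2,
    min_dive_depth_m       = 10,
    min_dive_duration_s    = 30,
    wiggle_min_excursion_m = 1,
    benthic_depth_ratio    = 0.9,
    benthic_cv_max         = 0.02,
    benthic_window_days    = 7L,
    sampling_interval_s    = 6,
    depth_resolution_m     = 0.5,
    accel_hz               = 20,
    basis_dim              = 15L
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_params(p)
  structure(p, class = "ip_params")
}

validate_params <- function(p) {
  scalars <- setdiff(names(p), "velocities_km_day")
  for (nm in scalars) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive number")
  }
  if (!length(p$velocities_km_day) || any(p$velocities_km_day <= 0))
    stop("velocities_km_day must be a non-empty positive vector")
  if (p$bottom_fraction >= 1) stop("bottom_fraction must be < 1")
  if (p$ice_threshold_pct > 100) stop("ice_threshold_pct must be <= 100")
  invisible(p)
}

#' @export
print.ip_params <- function(x, ...) {
  cat("icepulse analysis parameters:\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Serialize / restore analysis parameters
#'
#' Round-trips an [ip_params()] object through a plain named list (as written
#' to a run manifest or YAML config) without loss.
#'
#' @param p an `ip_params` object.
#' @param x a named list as produced by `params_to_list()`.
#' @return `params_to_list()` a named list; `params_from_list()` an
#'   `ip_params` object.
#' @export
params_to_list <- function(p) {
  stopifnot(inherits(p, "ip_params"))
  unclass(p)
}

#' @rdname params_to_list
#' @export
params_from_list <- function(x) {
  do.call(ip_params, as.list(x))
}
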