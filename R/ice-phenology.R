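#' Ross Island ice data locations and the Erebus Bay study site
#'
#' The five sea-ice data locations around Ross Island, ordered along the
#' coastline in the anticlockwise direction ice break-out progresses
#' (Northeast first, Southwest last), and the Erebus Bay study site.
#' Southern latitudes are negative.
#'
#' @return `ross_island_sources()`: data.frame with `name`, `lat`, `lon`;
#'   `erebus_bay()`: named numeric `c(lat, lon)`.
#' @export
ross_island_sources <- function() {
  data.frame(
    name = c("Northeast", "North", "Northwest", "West", "Southwest"),
    lat = c(-77.24, -77.20, -77.10, -77.32, -77.54),
    lon = c(169.10, 168.09, 166.09, 165.84, 165.58),
    stringsAsFactors = FALSE)
}

#' @rdname ross_island_sources
#' @export
erebus_bay <- function() c(lat = -77.6, lon = 167.0)

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param a,b coordinates as `c(lat, lon)` in decimal degrees.
#' @return distance in km.
#' @export
haversine_km <- function(a, b) {
  geosphere::distHaversine(c(a[["lon"]], a[["lat"]]),
                           c(b[["lon"]], b[["lat"]]), r = 6371)
}

#' Sea-ice break-out date of one cell
#'
#' The break-out date is the first date whose trailing `window_days`-day
#' running mean concentration (inclusive of that date) is strictly below
#' `threshold_pct`. Windows containing missing values are skipped with a
#' warning. Returns `NA` if the series never breaks out.
#'
#' @param dates vector of dates (or day indices), one per observation.
#' @param concentration daily % ice cover in `[0, 100]`.
#' @param window_days running-mean window length (days).
#' @param threshold_pct break-out threshold (% cover).
#' @return the break-out date (same class as `dates`), or `NA`.
#' @export
breakout_date <- function(dates, concentration, window_days = 7,
                          threshold_pct = 50) {
  stopifnot(length(dates) == length(concentration))
  if (length(concentration) < window_days)
    stop("need at least window_days observations")
  rm7 <- trailing_mean(concentration, window_days)
  if (any(is.na(rm7[window_days:length(rm7)]) &
          !is.na(concentration[window_days:length(concentration)])))
    warning("windows containing gaps were skipped")
  hit <- which(!is.na(rm7) & rm7 < threshold_pct)
  if (!length(hit)) return(dates[NA_integer_])
  dates[hit[1]]
}

#' Along-coast or direct advection path length
#'
#' Path distance from a named ice data location to the Erebus Bay study
#' site. `"direct"` is the great-circle distance; `"coastal"` follows the
#' anticlockwise coastline chain Northeast -> North -> Northwest -> West ->
#' Southwest -> Erebus Bay, starting at the given source.
#'
#' @param source name of one of the five data locations.
#' @param mode `"coastal"` (default) or `"direct"`.
#' @param sources source coordinate table ([ross_island_sources()]).
#' @param site study-site coordinate (`c(lat, lon)`).
#' @return path length in km.
#' @export
path_km <- function(source, mode = c("coastal", "direct"),
                    sources = ross_island_sources(), site = erebus_bay()) {
  mode <- match.arg(mode)
  i <- match(source, sources$name)
  if (is.na(i)) stop("unknown source name: ", source)
  pts <- rbind(as.matrix(sources[, c("lat", "lon")]),
               matrix(site, nrow = 1))
  if (mode == "direct")
    return(haversine_km(pts[i, ], pts[nrow(pts), ]))
  total <- 0
  for (j in i:(nrow(pts) - 1))
    total <- total + haversine_km(pts[j, ], pts[j + 1, ])
  total
}

#' Advection travel time in whole days
#'
#' Path length divided by current velocity, rounded to the nearest whole
#' day (ties round half up).
#'
#' @param path_km path length (km).
#' @param velocity current velocity (km/day), > 0.
#' @return integer number of days.
#' @export
advection_duration <- function(path_km, velocity) {
  if (any(velocity <= 0)) stop("velocity must be positive")
  as.integer(round_half_up(path_km / velocity))
}

#' Advection estimates for every source, velocity and year
#'
#' For each ice data location, detects the break-out date from the gridded
#' concentration series, computes the path length to the study site, the
#' whole-day travel time at each candidate velocity, the advective arrival
#' date and the bloom window (arrival to arrival + `bloom_days`). When the
#' ice table carries a `year` column, estimates are produced per year.
#' Sources whose series never break out are retained with `NA` dates.
#'
#' @param ice long-format ice table as from [generate_ice()] (`date`,
#'   `cell_id`, `concentration_pct`, optional `year`).
#' @param sources source coordinate table.
#' @param velocities candidate current velocities (km/day).
#' @param mode path mode, `"coastal"` or `"direct"`.
#' @param params an [ip_params()] object (break-out window/threshold and
#'   bloom length).
#' @return data.frame with one row per source x velocity (x year):
#'   `source`, `year`, `velocity`, `path_km`, `duration_days`,
#'   `breakout_date`, `arrival_date`, `bloom_start`, `bloom_end`.
#' @export
advection_table <- function(ice, sources = ross_island_sources(),
                            velocities = c(6.5, 10.3, 12),
                            mode = "coastal", params = ip_params()) {
  if (!"year" %in% names(ice)) ice$year <- NA_integer_
  out <- list(); k <- 0L
  for (yr in unique(ice$year)) {
    icy <- ice[ice$year %in% yr, , drop = FALSE]
    for (s in sources$name) {
      cell <- icy[icy$cell_id == s, , drop = FALSE]
      cell <- cell[order(cell$date), , drop = FALSE]
      bo <- if (nrow(cell) >= params$ice_window_days)
        breakout_date(cell$date, cell$concentration_pct,
                      params$ice_window_days, params$ice_threshold_pct)
      else cell$date[NA_integer_]
      pk <- path_km(s, mode, sources = sources)
      for (v in velocities) {
        k <- k + 1L
        dur <- advection_duration(pk, v)
        arrival <- bo + dur
        out[[k]] <- data.frame(
          source = s, year = yr, velocity = v, path_km = pk,
          duration_days = dur, breakout_date = bo, arrival_date = arrival,
          bloom_start = arrival, bloom_end = arrival + params$bloom_days,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
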