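#' Default demonstration configuration
#'
#' An all-synthetic configuration that exercises every pipeline stage at a
#' size that runs in well under a minute. All randomness derives from the
#' single `seed`.
#'
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @return a config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = file.path(tempdir(), "icepulse_demo"),
                        seed = 42L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    params = list(),
    scenario = list(n_seals = 3, days = 60, dives_per_day = 12,
                    shallow_start_day = 25),
    accel = list(capture_rate = 1.0, n_dives = 5),
    ice = list(breakout_days = c(Northeast = 30, North = 40, Northwest = 50,
                                 West = 60, Southwest = 70),
               n_days = 100),
    isotopes = list(n_seals = 9, n_segments = 5),
    mixing = list(chains = 4, iter = 12000, warmup = 3000)
  )
}

stage_fail <- function(stage, e, out_dir) {
  qdir <- file.path(out_dir, "quarantine")
  dir.create(qdir, showWarnings = FALSE, recursive = TRUE)
  made <- list.files(out_dir, full.names = TRUE)
  made <- made[!dir.exists(made)]
  file.copy(made, qdir, overwrite = TRUE)
  unlink(made)
  stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

wcsv <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' Run the full pipeline
#'
#' Executes simulate -> dives -> captures -> ice -> phenology -> isotopes as
#' configured, writing every stage output plus a run manifest (parameters,
#' seeds, package version, per-file row counts and content hashes) under
#' `config$out_dir`. Identical config and seed reproduce byte-identical CSV
#' outputs. A stage failure aborts with a stage-labelled error and moves any
#' partial outputs into an `out_dir/quarantine` directory.
#'
#' @param config a config list (see [demo_config()]) or the path to a YAML
#'   file containing one.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(demo_config(), config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(ip_params, cfg$params %||% list())
  seed <- as.integer(cfg$seed)

  # -- simulate ---------------------------------------------------------
  sim <- tryCatch({
    sc <- do.call(season_scenario, c(cfg$scenario, list(seed = seed)))
    tdr <- generate_tdr(sc, signal = TRUE)
    wcsv(tdr$records, file.path(out_dir, "tdr.csv"))
    wcsv(tdr$truth, file.path(out_dir, "truth_dives.csv"))
    jsonlite::write_json(list(scenario = unclass(sc)),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    tdr
  }, error = function(e) stage_fail("simulate", e, out_dir))

  # -- dives ------------------------------------------------------------
  dv <- tryCatch({
    dives <- process_tdr(sim$records, params)
    summaries <- daily_summaries(dives)
    wcsv(dives, file.path(out_dir, "dives.csv"))
    wcsv(summaries$sealdays, file.path(out_dir, "sealdays.csv"))
    wcsv(summaries$daily, file.path(out_dir, "daily.csv"))
    list(dives = dives, summaries = summaries)
  }, error = function(e) stage_fail("dives", e, out_dir))

  # -- captures ---------------------------------------------------------
  ev <- tryCatch({
    nd <- min(cfg$accel$n_dives %||% 5, nrow(sim$truth))
    acc <- generate_accel(sim$truth[seq_len(nd), ],
                          capture_rate = cfg$accel$capture_rate %||% 1,
                          hz = params$accel_hz, seed = seed + 1L)
    f <- highpass_surge(acc$records$surge_g, params$accel_hz,
                        params$highpass_cutoff_hz)
    events <- detect_prey_captures(acc$records$time, f,
                                   params$capture_threshold_g,
                                   params$capture_refractory_s)
    wcsv(events, file.path(out_dir, "events.csv"))
    events
  }, error = function(e) stage_fail("captures", e, out_dir))

  # -- ice --------------------------------------------------------------
  adv <- tryCatch({
    if (!is.null(cfg$ice$file)) {
      if (!file.exists(cfg$ice$file))
        stop("ice input file not found: ", cfg$ice$file)
      ice <- utils::read.csv(cfg$ice$file, stringsAsFactors = FALSE)
      ice$date <- as.Date(ice$date)
    } else {
      ice <- generate_ice(unlist(cfg$ice$breakout_days),
                          n_days = cfg$ice$n_days %||% 100,
                          seed = seed + 2L)
    }
    wcsv(ice, file.path(out_dir, "ice.csv"))
    adv <- advection_table(ice, velocities = params$velocities_km_day,
                           params = params)
    adv_out <- adv
    for (col in c("breakout_date", "arrival_date", "bloom_start",
                  "bloom_end"))
      adv_out[[col]] <- as.character(adv_out[[col]])
    wcsv(adv_out, file.path(out_dir, "advection.csv"))
    adv
  }, error = function(e) stage_fail("ice", e, out_dir))

  # -- phenology --------------------------------------------------------
  phen <- tryCatch({
    curve <- fit_seasonal_curve(dv$summaries$sealdays, covariate = "day",
                                k = params$basis_dim)
    wcsv(data.frame(day = curve$eval$x, fit = curve$eval$fit,
                    lo = curve$eval$lo, hi = curve$eval$hi),
         file.path(out_dir, "curve.csv"))
    shallow <- extract_shallow_period(curve, params$shallow_threshold_m)
    reg <- wiggle_depth_regression(dv$summaries$daily)
    jsonlite::write_json(
      list(shallow_period = shallow,
           aic = curve$aic),
      file.path(out_dir, "shallow_period.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
    jsonlite::write_json(
      list(wiggle_depth = reg[c("slope", "se", "intercept", "r2", "p", "n")]),
      file.path(out_dir, "regressions.json"), auto_unbox = TRUE, digits = NA)
    list(curve = curve, shallow = shallow, reg = reg)
  }, error = function(e) stage_fail("phenology", e, out_dir))

  # -- isotopes ---------------------------------------------------------
  mix <- tryCatch({
    iso <- generate_isotopes(n_seals = cfg$isotopes$n_seals %||% 9,
                             n_segments = cfg$isotopes$n_segments %||% 5,
                             seed = seed + 3L)
    wcsv(iso$whiskers, file.path(out_dir, "whiskers.csv"))
    wcsv(iso$sources, file.path(out_dir, "sources.csv"))
    fitm <- fit_mixing_model(iso$consumers, iso$sources,
                             chains = cfg$mixing$chains %||% 4,
                             iter = cfg$mixing$iter %||% 12000,
                             warmup = cfg$mixing$warmup %||% 3000,
                             seed = seed + 4L)
    wcsv(as.data.frame(fitm$p_draws),
         file.path(out_dir, "mixing_posterior.csv"))
    jsonlite::write_json(
      list(summary = fitm$summary, converged = fitm$converged,
           rhat = as.list(fitm$rhat)),
      file.path(out_dir, "mixing_summary.json"), auto_unbox = TRUE,
      digits = NA)
    fitm
  }, error = function(e) stage_fail("isotopes", e, out_dir))

  # -- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  paths <- file.path(out_dir, files)
  info <- data.frame(
    file = files,
    md5 = as.character(tools::md5sum(paths)),
    bytes = file.size(paths),
    rows = vapply(paths, function(p) {
      if (grepl("\\.csv$", p)) length(readLines(p)) - 1L else NA_integer_
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("icepulse")),
    seed = seed,
    params = params_to_list(params),
    files = info)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Verify a run manifest
#'
#' Recomputes the content hash of every file listed in a run's manifest and
#' reports mismatches or missing files.
#'
#' @param out_dir a directory written by [run_pipeline()].
#' @return data.frame with `file`, `ok`.
#' @export
verify_manifest <- function(out_dir) {
  man <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                             simplifyVector = TRUE)
  f <- man$files
  now <- as.character(tools::md5sum(file.path(out_dir, f$file)))
  data.frame(file = f$file, ok = !is.na(now) & now == f$md5,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Validate pipeline input files
#'
#' Schema and sanity checks for the pipeline's CSV inputs: column presence,
#' timestamp monotonicity, depth sign and quantization, sampling interval
#' (within 20% of the nominal 6 s), and ice concentration range. Problems
#' are reported, not thrown; each is labelled `"fatal"` or `"warning"`.
#'
#' @param paths named list of file paths; recognised names are `tdr`,
#'   `accel`, `ice`, `whiskers`, `sources`.
#' @param params an [ip_params()] object.
#' @return data.frame with `file`, `level`, `message`, `row` (first
#'   offending row or `NA`). Zero rows means no issues.
#' @export
validate_inputs <- function(paths, params = ip_params()) {
  issues <- list(); k <- 0L
  add <- function(file, level, message, row = NA_integer_) {
    k <<- k + 1L
    issues[[k]] <<- data.frame(file = file, level = level,
                               message = message, row = row,
                               stringsAsFactors = FALSE)
  }
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      add(file, "fatal", paste("missing column(s):",
                               paste(miss, collapse = ", ")))
      FALSE
    } else TRUE
  }
  for (nm in names(paths)) {
    f <- paths[[nm]]
    if (!file.exists(f)) { add(f, "fatal", "file not found"); next }
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (nm == "tdr") {
      if (!need(df, c("time", "depth_m"), f)) next
      if (any(df$depth_m < 0)) {
        add(f, "fatal", "negative depth", which(df$depth_m < 0)[1])
      }
      for (s in unique(df$seal_id %||% "all")) {
        tt <- if ("seal_id" %in% names(df)) df$time[df$seal_id == s]
        else df$time
        if (is.unsorted(tt, strictly = TRUE))
          add(f, "fatal", paste0("timestamps not strictly increasing (",
                                 s, ")"))
        dts <- diff(tt)
        m <- stats::median(dts)
        nom <- params$sampling_interval_s
        if (length(dts) && max(m, nom) / min(m, nom) >= 1.2)
          add(f, "warning", sprintf(
            "sampling interval %.2fs deviates 20%% or more from nominal %gs",
            m, nom))
      }
      q <- df$depth_m / params$depth_resolution_m
      if (any(abs(q - round(q)) > 1e-6))
        add(f, "warning", "depths not quantized to sensor resolution",
            which(abs(q - round(q)) > 1e-6)[1])
    } else if (nm == "accel") {
      if (!need(df, c("time", "surge_g"), f)) next
      if (any(!is.finite(df$surge_g)))
        add(f, "fatal", "non-finite surge values",
            which(!is.finite(df$surge_g))[1])
    } else if (nm == "ice") {
      if (!need(df, c("date", "cell_id", "concentration_pct"), f)) next
      bad <- df$concentration_pct < 0 | df$concentration_pct > 100
      if (any(bad))
        add(f, "fatal", "concentration outside [0, 100]", which(bad)[1])
    } else if (nm == "whiskers") {
      need(df, c("seal_id", "segment", "d15N", "d13C"), f)
    } else if (nm == "sources") {
      need(df, c("name", "mean_d15N", "sd_d15N", "mean_d13C", "sd_d13C"), f)
    } else {
      add(f, "warning", paste("unrecognised input kind:", nm))
    }
  }
  if (k == 0L)
    return(data.frame(file = character(0), level = character(0),
                      message = character(0), row = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
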