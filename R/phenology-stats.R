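#' Fit the seasonal depth curve with individual random effects
#'
#' Penalized cubic-spline smooth (basis order 4) of seal-day mean maximum
#' dive depth on a covariate — calendar day or days since advective
#' arrival — with a Gaussian random intercept per seal. The default smooth
#' is an adaptive cubic P-spline (`bs = "ad"`, basis dimension 15), which
#' lets the penalty vary along the season: the trajectory has steep ramps
#' and a flat mid-summer plateau, and a single global penalty either
#' oversmooths the plateau depth or undersmooths everything else. A
#' fixed-penalty order-4 B-spline (`bs = "bs"`) is available, and is used
#' automatically when the covariate has too few distinct values to support
#' the adaptive basis. Smoothness is selected by maximum likelihood
#' (`"ML"`, the default, so AICs are comparable across fixed-effect
#' structures) or `"REML"`. The fitted population-level curve (random
#' intercepts excluded) is evaluated with a pointwise 95% CI over the
#' observed covariate range only.
#'
#' @param sealdays data.frame with `seal_id`, the covariate column, and
#'   `mean_max_depth`.
#' @param covariate name of the covariate column (default `"day"`).
#' @param k spline basis dimension.
#' @param method smoothing-parameter selection, `"ML"` or `"REML"`.
#' @param bs smooth class: `"ad"` (adaptive, default) or `"bs"`.
#' @param grid_n number of evaluation points.
#' @return object of class `season_curve`: list with `eval` (data.frame
#'   `x`, `fit`, `lo`, `hi`), `aic`, `covariate`, `method`, `ranef`
#'   (per-seal intercepts) and `model` (the underlying [mgcv::gam] fit).
#' @export
fit_seasonal_curve <- function(sealdays, covariate = "day", k = 15,
                               method = c("ML", "REML"), bs = c("ad", "bs"),
                               grid_n = 200) {
  method <- match.arg(method)
  bs <- match.arg(bs)
  stopifnot(covariate %in% names(sealdays),
            "mean_max_depth" %in% names(sealdays))
  x <- sealdays[[covariate]]
  if (length(unique(x)) < 2)
    stop("rank-deficient design: all observations share one date")
  dat <- data.frame(y = sealdays$mean_max_depth, x = x,
                    seal_f = factor(sealdays$seal_id))
  k_eff <- max(4, min(k, length(unique(x)) - 1))
  if (bs == "ad" && (k_eff < 10 || length(unique(x)) < 20)) bs <- "bs"
  use_re <- nlevels(dat$seal_f) >= 2
  smtxt <- if (bs == "ad") sprintf("s(x, k = %d, bs = 'ad')", k_eff)
  else sprintf("s(x, k = %d, bs = 'bs', m = c(3, 2))", k_eff)
  form <- stats::as.formula(paste(
    "y ~", smtxt, if (use_re) "+ s(seal_f, bs = 're')" else ""))
  if (!use_re)
    warning("single seal: fitting without a random intercept")
  fit <- mgcv::gam(form, data = dat, method = method)
  grid <- data.frame(x = seq(min(x), max(x), length.out = grid_n),
                     seal_f = factor(levels(dat$seal_f)[1],
                                     levels = levels(dat$seal_f)))
  pr <- mgcv::predict.gam(fit, newdata = grid, se.fit = TRUE,
                          exclude = if (use_re) "s(seal_f)" else NULL,
                          newdata.guaranteed = TRUE)
  ranef <- if (use_re) {
    cf <- stats::coef(fit)
    re <- cf[grepl("^s\\(seal_f\\)", names(cf))]
    stats::setNames(as.numeric(re), levels(dat$seal_f))
  } else NULL
  out <- list(
    eval = data.frame(x = grid$x, fit = as.numeric(pr$fit),
                      lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
                      hi = as.numeric(pr$fit + 1.96 * pr$se.fit)),
    aic = stats::AIC(fit), covariate = covariate, method = method,
    ranef = ranef, model = fit)
  class(out) <- "season_curve"
  out
}

#' @export
print.season_curve <- function(x, ...) {
  cat(sprintf(
    "Seasonal depth curve on '%s' (%s): fit range %.1f-%.1f m, AIC %.1f\n",
    x$covariate, x$method, min(x$eval$fit), max(x$eval$fit), x$aic))
  invisible(x)
}

#' @export
summary.season_curve <- function(object, ...) {
  s <- list(curve = object,
            shallowest = object$eval[which.min(object$eval$fit), ],
            gam_summary = summary(object$model))
  class(s) <- "summary.season_curve"
  s
}

#' @export
print.summary.season_curve <- function(x, ...) {
  print(x$curve)
  cat(sprintf("  shallowest point: %.1f m at x = %.1f\n",
              x$shallowest$fit, x$shallowest$x))
  invisible(x)
}

#' @export
predict.season_curve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$eval$fit)
  lev <- levels(object$model$model$seal_f)
  nd <- data.frame(x = newdata, seal_f = factor(lev[1], levels = lev))
  as.numeric(mgcv::predict.gam(object$model, newdata = nd,
                               exclude = "s(seal_f)",
                               newdata.guaranteed = TRUE))
}

#' @export
plot.season_curve <- function(x, ...) {
  e <- x$eval
  graphics::plot(e$x, e$fit, type = "n", ylim = rev(range(c(e$lo, e$hi))),
                 xlab = x$covariate, ylab = "mean max dive depth (m)", ...)
  graphics::polygon(c(e$x, rev(e$x)), c(e$lo, rev(e$hi)),
                    col = "grey85", border = NA)
  graphics::lines(e$x, e$fit, lwd = 2)
  invisible(x)
}

#' @export
logLik.season_curve <- function(object, ...) stats::logLik(object$model)

#' Extract the shallowing period from a fitted curve
#'
#' The shallowing period is the longest contiguous run of evaluation points
#' whose fitted depth does not exceed `threshold_m` (default 140 m); the
#' shallowest point is the minimum of the fitted curve within that run.
#'
#' @param curve a [fit_seasonal_curve()] result.
#' @param threshold_m shallow-period depth threshold (m).
#' @return `NULL` if the curve never reaches the threshold, otherwise a list
#'   with `start`, `end`, `duration` (covariate units), `shallowest_x`,
#'   `shallowest_depth`.
#' @export
extract_shallow_period <- function(curve, threshold_m = 140) {
  e <- curve$eval
  below <- e$fit <= threshold_m
  if (!any(below)) return(NULL)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  lens <- e$x[ends[cand]] - e$x[starts[cand]]
  j <- cand[which.max(lens)]
  i0 <- starts[j]; i1 <- ends[j]
  seg <- e[i0:i1, ]
  m <- which.min(seg$fit)
  list(start = e$x[i0], end = e$x[i1], duration = e$x[i1] - e$x[i0],
       shallowest_x = seg$x[m], shallowest_depth = seg$fit[m])
}

# Shared OLS summary used by the regression utilities.
ols_result <- function(fit, one_tailed = FALSE, level = 0.95) {
  co <- summary(fit)$coefficients
  slope <- co[2, 1]; se <- co[2, 2]; tval <- co[2, 3]
  dfree <- fit$df.residual
  p <- if (one_tailed) stats::pt(tval, dfree, lower.tail = FALSE)
  else co[2, 4]
  tq <- stats::qt(1 - (1 - level) / 2, dfree)
  list(slope = slope, se = se, intercept = co[1, 1],
       r2 = summary(fit)$r.squared, p = p,
       p_type = if (one_tailed) "one-tailed (slope > 0)" else "two-tailed",
       ci = slope + c(-1, 1) * tq * se, n = stats::nobs(fit))
}

#' Cross-year regression of shallowest depth on shallowest date
#'
#' Ordinary least squares of the per-year shallowest fitted depth on the
#' per-year date of shallowest diving, with a one-tailed p-value for a
#' positive slope (shallowest diving is deeper in years when it occurs
#' later).
#'
#' @param points data.frame with `date` (numeric) and `depth` (m), one row
#'   per year.
#' @return list with `slope`, `se`, `intercept`, `r2`, `p` (one-tailed),
#'   `ci`, `n`.
#' @export
cross_year_regression <- function(points) {
  if (nrow(points) < 3) stop("need at least 3 years")
  ols_result(stats::lm(depth ~ date, data = points), one_tailed = TRUE)
}

#' Daily wiggle rate vs daily mean depth
#'
#' OLS of the across-seal daily wiggle rate (wiggles per minute of bottom
#' time) on the across-seal daily mean maximum dive depth.
#'
#' @param daily across-seal daily table (needs `mean_max_depth`,
#'   `wiggle_rate`).
#' @return OLS result list as in [cross_year_regression()] (two-tailed p).
#' @export
wiggle_depth_regression <- function(daily) {
  if (nrow(daily) < 10) stop("need at least 10 days")
  if (stats::sd(daily$mean_max_depth) == 0)
    stop("zero-variance depth")
  ols_result(stats::lm(wiggle_rate ~ mean_max_depth, data = daily))
}

#' Generic paired regression (e.g. per-seal wiggle rate vs mass gain)
#'
#' OLS of `y` on `x` with slope CI; used for ancillary relationships such as
#' per-seal total wiggle rate predicting mass gain per hour diving.
#'
#' @param x,y paired numeric vectors.
#' @return OLS result list (two-tailed p).
#' @export
ancillary_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need at least 3 pairs")
  ols_result(stats::lm(y ~ x))
}

#' Feeding-rate and efficiency contrasts across the shallow period
#'
#' Defines early-deep as the first `flank_days` observed days before the
#' shallowing period, and late-deep as the last `flank_days` observed days
#' after it. Returns the percent change of mean feeding rate and mean
#' diving efficiency from early-deep to the shallow period and from the
#' shallow period to late-deep, plus a compound change — the product of the
#' early->shallow feeding-rate and efficiency ratios — measuring how much
#' more bottom-phase feeding a shallow-period dive delivers per unit dive
#' time than an early-summer deep dive.
#'
#' @param daily across-seal daily table (needs `day`, `efficiency`, and
#'   `feeding_rate` or `wiggle_rate` as the feeding proxy).
#' @param shallow an [extract_shallow_period()] result.
#' @param flank_days length of the deep flanks (days).
#' @return list with `feed_early_to_shallow_pct`,
#'   `feed_shallow_to_late_pct`, `eff_early_to_shallow_pct`,
#'   `eff_shallow_to_late_pct`, `compound_efficiency_pct`, and the period
#'   means.
#' @export
period_contrasts <- function(daily, shallow, flank_days = 10) {
  feed <- if ("feeding_rate" %in% names(daily)) daily$feeding_rate
  else daily$wiggle_rate
  pre <- daily$day < shallow$start
  post <- daily$day > shallow$end
  mid <- daily$day >= shallow$start & daily$day <= shallow$end
  pre_days <- sort(daily$day[pre])
  post_days <- sort(daily$day[post])
  if (length(pre_days) < flank_days || length(post_days) < flank_days)
    warning("fewer than flank_days observations on a deep flank; ",
            "partial contrast")
  early <- pre & daily$day <= (min(pre_days) + flank_days - 1)
  late <- post & daily$day >= (max(post_days) - flank_days + 1)
  pct <- function(a, b) 100 * (b - a) / a
  means <- list(feed_early = mean(feed[early]), feed_shallow = mean(feed[mid]),
                feed_late = mean(feed[late]), eff_early = mean(daily$efficiency[early]),
                eff_shallow = mean(daily$efficiency[mid]),
                eff_late = mean(daily$efficiency[late]))
  f1 <- pct(means$feed_early, means$feed_shallow)
  f2 <- pct(means$feed_shallow, means$feed_late)
  e1 <- pct(means$eff_early, means$eff_shallow)
  e2 <- pct(means$eff_shallow, means$eff_late)
  list(feed_early_to_shallow_pct = f1, feed_shallow_to_late_pct = f2,
       eff_early_to_shallow_pct = e1, eff_shallow_to_late_pct = e2,
       compound_efficiency_pct = 100 * ((1 + f1 / 100) * (1 + e1 / 100) - 1),
       means = means)
}

#' Compare calendar-day and advective-arrival covariates by AIC
#'
#' Fits the seasonal depth curve twice per advection hypothesis — once on
#' calendar day, once on days since the advected phytoplankton arrival for
#' that source and velocity (the arrival date varies by year) — and reports
#' `delta_aic = AIC(calendar) - AIC(arrival)`. Positive values favour the
#' arrival-aligned model. Both fits use ML so the AICs are comparable.
#'
#' @param sealdays data.frame with `seal_id`, `year`, `day`,
#'   `mean_max_depth`.
#' @param arrivals data.frame with `source`, `velocity`, `year`,
#'   `arrival_day` (same day units as `sealdays$day`).
#' @param k spline basis dimension.
#' @return data.frame with `source`, `velocity`, `aic_calendar`,
#'   `aic_arrival`, `delta_aic`.
#' @export
compare_covariates <- function(sealdays, arrivals, k = 10) {
  stopifnot(all(c("year", "day") %in% names(sealdays)))
  if (length(unique(sealdays$year)) < 2)
    stop("need at least 2 years: with one year the covariates are collinear")
  aic_cal <- fit_seasonal_curve(sealdays, covariate = "day", k = k,
                                method = "ML")$aic
  combos <- unique(arrivals[, c("source", "velocity")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    a <- arrivals[arrivals$source == combos$source[i] &
                    arrivals$velocity == combos$velocity[i], ]
    arr <- a$arrival_day[match(sealdays$year, a$year)]
    if (any(is.na(arr)))
      stop("missing arrival day for some year (source ",
           combos$source[i], ")")
    sd2 <- sealdays
    sd2$days_since_arrival <- sd2$day - arr
    aic_arr <- fit_seasonal_curve(sd2, covariate = "days_since_arrival",
                                  k = k, method = "ML")$aic
    out[[i]] <- data.frame(source = combos$source[i],
                           velocity = combos$velocity[i],
                           aic_calendar = aic_cal, aic_arrival = aic_arr,
                           delta_aic = aic_cal - aic_arr,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
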