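#' Assign dates to whisker segments
#'
#' Linear-growth time-stamping: segment `i` of `n` (numbered from the tip,
#' grown first, to the base) is dated at the midpoint of the i-th of `n`
#' equal sub-intervals of the deployment window.
#'
#' @param n_segments number of segments.
#' @param deploy_date,recover_date deployment window (deploy before
#'   recover).
#' @return data.frame with `segment` and `date`.
#' @export
assign_segment_dates <- function(n_segments, deploy_date, recover_date) {
  if (n_segments < 1) stop("need at least 1 segment")
  deploy_date <- as.Date(deploy_date); recover_date <- as.Date(recover_date)
  if (!deploy_date < recover_date)
    stop("deploy_date must precede recover_date")
  span <- as.numeric(recover_date - deploy_date)
  data.frame(segment = seq_len(n_segments),
             date = deploy_date + (seq_len(n_segments) - 0.5) / n_segments * span)
}

#' Temporal trend in whisker isotope values
#'
#' Random-intercept linear model of each isotope on date (days since 1
#' January of the first year observed), with the individual seal as the
#' random effect; used to test whether diet shifted across the season.
#'
#' @param samples data.frame with `seal_id`, `date`, and isotope columns
#'   `d15N` and/or `d13C`.
#' @param level confidence level for the Wald slope interval.
#' @return named list (one element per isotope) of lists with `slope`
#'   (permil/day), `se`, `ci`, `covers_zero`.
#' @export
isotope_trend <- function(samples, level = 0.95) {
  if (length(unique(samples$seal_id)) < 2) stop("need at least 2 seals")
  if (length(unique(samples$date)) < 3) stop("need at least 3 dates")
  jan1 <- as.Date(paste0(format(min(as.Date(samples$date)), "%Y"), "-01-01"))
  samples$doy <- as.numeric(as.Date(samples$date) - jan1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list()
  for (iso in intersect(c("d15N", "d13C"), names(samples))) {
    dat <- data.frame(y = samples[[iso]], doy = samples$doy,
                      seal_id = samples$seal_id)
    fit <- lme4::lmer(y ~ doy + (1 | seal_id), data = dat)
    co <- summary(fit)$coefficients
    slope <- co["doy", "Estimate"]; se <- co["doy", "Std. Error"]
    ci <- slope + c(-1, 1) * z * se
    out[[iso]] <- list(slope = slope, se = se, ci = ci,
                       covers_zero = ci[1] <= 0 && ci[2] >= 0)
  }
  out
}

# Log posterior density of the mixing model in unconstrained coordinates
# theta = (z[1..S-1], log sigma[1..K]); z is the additive log-ratio
# transform of the diet proportions (reference = last source). The Dirichlet
# prior combines with the ALR Jacobian into sum(alpha * log p); sigma has a
# half-normal prior with its own log-scale Jacobian.
mixing_log_post <- function(theta, x, mu, vsum, alpha, sigma_scale) {
  S <- nrow(mu); K <- ncol(mu)
  z <- c(theta[seq_len(S - 1)], 0)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  if (any(p <= 0)) return(-Inf)
  log_sig <- theta[S:(S + K - 1)]
  sig2 <- exp(2 * log_sig)
  m <- as.numeric(p %*% mu)
  v <- as.numeric((p^2) %*% vsum) + sig2
  ll <- 0
  for (k in seq_len(K))
    ll <- ll + sum(stats::dnorm(x[, k], m[k], sqrt(v[k]), log = TRUE))
  ll + sum(alpha * log(p)) +
    sum(stats::dnorm(exp(log_sig), 0, sigma_scale, log = TRUE) + log_sig)
}

#' Bayesian stable-isotope diet mixing model
#'
#' Estimates diet proportions `p` over a set of prey source groups from
#' consumer isotope values. The observation model for consumer replicate
#' `j` and isotope `k` is Normal with mean `sum_s p_s (mu_sk + lambda_sk)`
#' and variance `sum_s p_s^2 (omega_sk^2 + tau_sk^2) + sigma_k^2`, where
#' `mu/omega` are the source means/SDs, `lambda/tau` the trophic enrichment
#' factor means/SDs, and `sigma_k` a residual SD per isotope. Priors:
#' `p ~ Dirichlet(alpha)` (uniform by default) and half-normal `sigma`.
#' The posterior is sampled by adaptive random-walk Metropolis on an
#' additive log-ratio transform of the simplex, in several independent
#' chains; a split-chain scale-reduction diagnostic is computed and the
#' result flagged if any parameter exceeds 1.05.
#'
#' @param consumers data.frame (or matrix) of consumer isotope values with
#'   columns named `d15N` and/or `d13C` (typically per-seal whisker means).
#' @param sources source table as from [synthetic_prey_sources()]; only the
#'   columns for the isotopes present in `consumers` are required.
#' @param alpha Dirichlet concentration, scalar or one value per source.
#' @param chains number of MCMC chains.
#' @param iter post-warmup draws per chain.
#' @param warmup warm-up (adaptation) iterations per chain, discarded.
#' @param seed integer seed.
#' @param sigma_scale half-normal prior scale for the residual SDs (permil).
#' @return object of class `mixing_fit`: list with `p_draws` (draws x
#'   sources matrix, every row on the simplex), `sigma_draws`, `summary`
#'   (per-source posterior median and 95% credible interval), `rhat`,
#'   `converged`, `isotopes`, `sources`.
#' @export
fit_mixing_model <- function(consumers, sources, alpha = 1, chains = 4,
                             iter = 5000, warmup = 2000, seed = 1L,
                             sigma_scale = 5) {
  isotopes <- intersect(c("d15N", "d13C"), colnames(consumers))
  if (!length(isotopes)) stop("consumers must have a d15N or d13C column")
  S <- nrow(sources)
  if (S < 2) stop("need at least 2 sources")
  x <- as.matrix(as.data.frame(consumers)[, isotopes, drop = FALSE])
  if (!all(is.finite(x))) stop("consumer values must be finite")
  mu <- vsum <- matrix(0, S, length(isotopes))
  for (k in seq_along(isotopes)) {
    iso <- isotopes[k]
    mu[, k] <- sources[[paste0("mean_", iso)]] +
      sources[[paste0("tef_", iso, "_mean")]]
    vsum[, k] <- sources[[paste0("sd_", iso)]]^2 +
      sources[[paste0("tef_", iso, "_sd")]]^2
  }
  if (length(alpha) == 1) alpha <- rep(alpha, S)
  stopifnot(length(alpha) == S)
  K <- length(isotopes)
  npar <- S - 1 + K
  set.seed(seed)
  kept_p <- vector("list", chains)
  kept_sig <- vector("list", chains)
  for (ch in seq_len(chains)) {
    theta <- c(stats::rnorm(S - 1, 0, 0.5),
               log(stats::runif(K, 0.2, 1)))
    lp <- mixing_log_post(theta, x, mu, vsum, alpha, sigma_scale)
    step <- 0.4
    L <- diag(npar)                # proposal shape (Cholesky factor)
    total <- warmup + iter
    P <- matrix(NA_real_, iter, S)
    SG <- matrix(NA_real_, iter, K)
    W <- matrix(NA_real_, warmup, npar)
    acc_win <- 0L
    for (it in seq_len(total)) {
      prop <- theta + step * as.numeric(stats::rnorm(npar) %*% L)
      lp_prop <- mixing_log_post(prop, x, mu, vsum, alpha, sigma_scale)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; acc_win <- acc_win + 1L
      }
      if (it <= warmup) {
        W[it, ] <- theta
        if (it %% 50L == 0L) {
          step <- step * exp(acc_win / 50 - 0.25)
          acc_win <- 0L
          # adapt the proposal shape to the posterior: the diet-proportion
          # likelihood often has a collinearity ridge between similar
          # sources that a spherical proposal traverses slowly
          if (it >= 300L) {
            recent <- W[max(1L, it - 999L):it, , drop = FALSE]
            C <- stats::cov(recent) + diag(1e-8, npar)
            L <- tryCatch(chol(C), error = function(e) L)
          }
        }
      }
      if (it > warmup) {
        z <- c(theta[seq_len(S - 1)], 0); z <- z - max(z)
        P[it - warmup, ] <- exp(z) / sum(exp(z))
        SG[it - warmup, ] <- exp(theta[S:(S + K - 1)])
      }
    }
    kept_p[[ch]] <- P
    kept_sig[[ch]] <- SG
  }
  p_draws <- do.call(rbind, kept_p)
  colnames(p_draws) <- sources$name
  sigma_draws <- do.call(rbind, kept_sig)
  colnames(sigma_draws) <- paste0("sigma_", isotopes)
  rhat <- c(
    vapply(seq_len(S), function(j)
      split_rhat(lapply(kept_p, function(m) m[, j])), numeric(1)),
    vapply(seq_len(K), function(j)
      split_rhat(lapply(kept_sig, function(m) m[, j])), numeric(1)))
  names(rhat) <- c(sources$name, colnames(sigma_draws))
  converged <- all(is.na(rhat) | rhat < 1.05)
  if (!converged)
    warning("MCMC convergence diagnostic above 1.05; ",
            "inspect rhat and increase iterations")
  qs <- t(apply(p_draws, 2, stats::quantile,
                probs = c(0.5, 0.025, 0.975), names = FALSE))
  out <- list(
    p_draws = p_draws, sigma_draws = sigma_draws,
    summary = data.frame(source = sources$name, median = qs[, 1],
                         lo95 = qs[, 2], hi95 = qs[, 3],
                         rhat = rhat[seq_len(S)], row.names = NULL,
                         stringsAsFactors = FALSE),
    rhat = rhat, converged = converged, isotopes = isotopes,
    sources = sources,
    settings = list(alpha = alpha, chains = chains, iter = iter,
                    warmup = warmup, seed = seed,
                    sigma_scale = sigma_scale))
  class(out) <- "mixing_fit"
  out
}

# Split-chain potential scale reduction factor. `chains` is a list of
# equal-length numeric vectors; each is split in half before the standard
# between/within variance ratio.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[(n + 1L):(2L * n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat(sprintf("Isotope mixing model: %d sources, %d isotope(s), %d draws%s\n",
              nrow(x$summary), length(x$isotopes), nrow(x$p_draws),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  df <- x$summary
  df$median <- sprintf("%.3f", df$median)
  df$lo95 <- sprintf("%.3f", df$lo95)
  df$hi95 <- sprintf("%.3f", df$hi95)
  df$rhat <- sprintf("%.3f", df$rhat)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mixing_fit <- function(object, ...) object$summary

#' @export
coef.mixing_fit <- function(object, ...) {
  stats::setNames(object$summary$median, object$summary$source)
}

#' @export
plot.mixing_fit <- function(x, ...) {
  S <- ncol(x$p_draws)
  op <- graphics::par(mfrow = c(1, S), mar = c(4, 3, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(S)) {
    d <- stats::density(x$p_draws[, j], from = 0, to = 1)
    graphics::plot(d, main = colnames(x$p_draws)[j],
                   xlab = "diet proportion", ...)
  }
  invisible(x)
}
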