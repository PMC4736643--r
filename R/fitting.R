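#' Fit results
#'
#' Container returned by the fitting functions: the family and method
#' used, the parameter estimates on the natural scale, the final
#' objective value (negative log-likelihood for the ML methods, residual
#' sum of squares for CD-NLS), an honest convergence flag, and the
#' number of observations used.
#'
#' @param family Distribution family.
#' @param method One of `"lower"`, `"mid"`, `"upper"`, `"cd_ml"`,
#'   `"cd_nls"`.
#' @param mu_hat,sigma_hat Parameter estimates (`NA` if unconverged).
#' @param objective Final objective value.
#' @param converged Logical.
#' @param n_used Number of propagules (or cumulative points) used.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(family, method, mu_hat = NA_real_,
                       sigma_hat = NA_real_, objective = NA_real_,
                       converged = FALSE, n_used = 0L) {
  structure(list(family = family, method = method,
                 mu_hat = mu_hat, sigma_hat = sigma_hat,
                 objective = objective, converged = converged,
                 n_used = as.integer(n_used)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s / %s: mu_hat = %.5g, sigma_hat = %.5g\n",
              x$family, x$method, x$mu_hat, x$sigma_hat))
  cat(sprintf("objective = %.6g, converged = %s, n_used = %d\n",
              x$objective, x$converged, x$n_used))
  invisible(x)
}

#' Estimated distribution of a converged fit
#'
#' @param fit A converged `fit_result`.
#' @return A [retention_dist()] with the estimated parameters.
#' @export
fitted_dist <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (!isTRUE(fit$converged))
    stop("fit did not converge; no estimated distribution", call. = FALSE)
  retention_dist(fit$family, fit$mu_hat, fit$sigma_hat)
}

# ---- bound-based methods ---------------------------------------------

#' Expand a censored sample to interval-bound points
#'
#' The three bound-based fitting methods treat a chosen point of each
#' censoring interval (its lower bound, midpoint or upper bound) as if
#' it were the exact retention time. Each interval contributes `count`
#' copies of that point; right-censored propagules have no natural point
#' and are excluded. The zero lower bound of the first interval is
#' replaced by a small positive floor (`zero_floor`, default 0.01 h) so
#' that log-densities stay defined.
#'
#' @param sample A [censored_sample()].
#' @param bound `"lower"`, `"mid"` or `"upper"`.
#' @param zero_floor Replacement for a zero lower bound, in hours.
#' @return A numeric vector of pseudo-exact retention times.
#' @export
expand_to_points <- function(sample, bound = c("lower", "mid", "upper"),
                             zero_floor = 0.01) {
  check_sample(sample)
  bound <- match.arg(bound)
  iv <- sample$intervals
  pts <- switch(bound,
                lower = pmax(iv$lower, zero_floor),
                mid   = (iv$lower + iv$upper) / 2,
                upper = iv$upper)
  rep(pts, times = iv$count)
}

# Uncensored negative log-likelihood of points under (mu, sigma).
points_nll <- function(par, x, family) {
  d <- try(retention_dist(family, par[1L], par[2L]), silent = TRUE)
  if (inherits(d, "try-error")) return(Inf)
  ll <- sum(log(dretention(d, x)))
  if (!is.finite(ll)) return(Inf)
  -ll
}

#' Bound-based maximum-likelihood fit
#'
#' Expands the censored sample to interval-bound points (lower, mid or
#' upper) and fits the family by ordinary (uncensored) maximum
#' likelihood, i.e. by maximising the sum of log densities at those
#' points. This is the classical — and biased — way interval data are
#' fitted when censoring is ignored.
#'
#' For the lognormal family the ML estimate is closed form
#' (`mu_hat = mean(log t)`, `sigma_hat` the population sd of `log t`);
#' gamma and Weibull fits use a quasi-Newton search from
#' method-of-moments starting values, on the log-parameter scale.
#'
#' @inheritParams expand_to_points
#' @param family Distribution family to fit.
#' @return A `fit_result` with `method` set to the bound used.
#' @export
fit_bound_ml <- function(sample, family = c("lognormal", "gamma", "weibull"),
                         bound = c("lower", "mid", "upper"),
                         zero_floor = 0.01) {
  family <- match.arg(family)
  bound <- match.arg(bound)
  x <- expand_to_points(sample, bound, zero_floor = zero_floor)
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L)
    return(fit_result(family, bound, n_used = n))  # degenerate likelihood

  if (family == "lognormal") {
    lx <- log(x)
    mu <- mean(lx)
    sg <- sqrt(mean((lx - mu)^2))            # ML (population) sd
    return(fit_result(family, bound, mu, sg,
                      objective = points_nll(c(mu, sg), x, "lognormal"),
                      converged = TRUE, n_used = n))
  }

  start <- moment_start(x, family)
  opt <- optimize_nat(function(p) points_nll(p, x, family), start, family)
  fit_result(family, bound, opt$par[1L], opt$par[2L],
             objective = opt$value, converged = opt$converged, n_used = n)
}

# Method-of-moments starting values on (pseudo-)exact points.
moment_start <- function(x, family) {
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= 0) v <- (0.1 * m)^2
  switch(family,
    lognormal = {
      lx <- log(x)
      c(mean(lx), max(stats::sd(lx), 0.05))
    },
    gamma = c(max(m^2 / v, 1e-3), max(m / v, 1e-6)),
    weibull = {
      k <- (sqrt(v) / m)^(-1.086)            # standard cv approximation
      k <- min(max(k, 0.1), 50)
      c(k, m / gamma(1 + 1 / k))
    })
}

# Local minimisation of `fn` over (mu, sigma) with positivity enforced
# by a log transform (mu left unconstrained for the lognormal family).
optimize_nat <- function(fn, start, family, maxit = 500) {
  to_theta <- function(p)
    if (family == "lognormal") c(p[1L], log(p[2L])) else log(p)
  from_theta <- function(th)
    if (family == "lognormal") c(th[1L], exp(th[2L])) else exp(th)
  obj <- function(th) fn(from_theta(th))
  opt <- stats::optim(to_theta(start), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = maxit))
  par <- from_theta(opt$par)
  list(par = par, value = opt$value,
       converged = opt$convergence == 0 && is.finite(opt$value) &&
         all(is.finite(par)))
}

# ---- cumulative-distribution methods ---------------------------------

#' Interval-censored negative log-likelihood
#'
#' The log-likelihood of a censored sample under a candidate
#' distribution sums, over censoring intervals, `count * log(F(upper) -
#' F(lower))`, plus a survival term `right_censored * log(1 -
#' F(horizon))` for propagules never retrieved. Returns `+Inf` (rather
#' than erroring) when a positive count falls in a zero-probability
#' interval or the parameters are invalid, so optimizers can retreat.
#'
#' @param params Numeric `c(mu, sigma)` on the natural scale.
#' @param sample A [censored_sample()].
#' @param family Distribution family.
#' @return The negative log-likelihood (finite or `+Inf`).
#' @export
censored_nll <- function(params, sample,
                         family = c("lognormal", "gamma", "weibull")) {
  check_sample(sample)
  family <- match.arg(family)
  d <- try(retention_dist(family, params[1L], params[2L]), silent = TRUE)
  if (inherits(d, "try-error")) return(Inf)
  iv <- sample$intervals
  p <- pretention(d, iv$upper) - pretention(d, iv$lower)
  ll <- 0
  pos <- iv$count > 0
  if (any(pos)) {
    if (any(p[pos] <= 0)) return(Inf)
    ll <- ll + sum(iv$count[pos] * log(p[pos]))
  }
  if (sample$right_censored > 0) {
    s <- 1 - pretention(d, sample$horizon)
    if (s <= 0) return(Inf)
    ll <- ll + sample$right_censored * log(s)
  }
  if (!is.finite(ll)) return(Inf)
  -ll
}

#' Cumulative-distribution maximum-likelihood fit (CD-ML)
#'
#' Fits the family to the censored sample by maximising the
#' interval-censored likelihood ([censored_nll()]): each propagule
#' contributes the probability mass of the interval in which it was
#' retrieved, and right-censored propagules contribute the survival
#' probability beyond the horizon. This is the recommended method for
#' interval-censored retention data.
#'
#' @inheritParams fit_bound_ml
#' @return A `fit_result` with `method = "cd_ml"`; `objective` is the
#'   minimised negative log-likelihood.
#' @export
fit_cd_ml <- function(sample, family = c("lognormal", "gamma", "weibull")) {
  family <- match.arg(family)
  check_sample(sample)
  if (sum(sample$intervals$count > 0) < 2L)
    return(fit_result(family, "cd_ml", n_used = sample$n_total))

  start <- cd_start(sample, family)
  opt <- optimize_nat(function(p) censored_nll(p, sample, family),
                      start, family)
  fit_result(family, "cd_ml", opt$par[1L], opt$par[2L],
             objective = opt$value, converged = opt$converged,
             n_used = sample$n_total)
}

# Weighted method-of-moments starts from interval midpoints; avoids
# materialising one point per propagule (counts may be huge).
cd_start <- function(sample, family) {
  iv <- sample$intervals
  mids <- pmax((iv$lower + iv$upper) / 2, 0.01)
  w <- iv$count
  if (sum(w > 0) < 2L) {
    # degenerate mids: fall back to scale-informed defaults
    return(switch(family,
                  lognormal = c(log(max(mids[which.max(w)], 1)), 0.5),
                  gamma = c(2, 2 / max(mids[which.max(w)], 1)),
                  weibull = c(1.5, max(mids[which.max(w)], 1))))
  }
  m <- stats::weighted.mean(mids, w)
  v <- sum(w * (mids - m)^2) / max(sum(w) - 1, 1)
  if (!is.finite(v) || v <= 0) v <- (0.1 * m)^2
  switch(family,
    lognormal = {
      lm <- stats::weighted.mean(log(mids), w)
      lv <- sum(w * (log(mids) - lm)^2) / max(sum(w) - 1, 1)
      c(lm, max(sqrt(lv), 0.05))
    },
    gamma = c(max(m^2 / v, 1e-3), max(m / v, 1e-6)),
    weibull = {
      k <- (sqrt(v) / m)^(-1.086)
      k <- min(max(k, 0.1), 50)
      c(k, m / gamma(1 + 1 / k))
    })
}

#' Empirical cumulative proportions of a censored sample
#'
#' One point per censoring interval, at its upper bound, whose value is
#' the running proportion of propagules retrieved by that time. The last
#' point equals 1 exactly when no propagule was right-censored.
#'
#' @param sample A [censored_sample()].
#' @return A data frame with columns `upper` (hours) and `cum_prop`.
#' @export
empirical_cumulative <- function(sample) {
  check_sample(sample)
  stopifnot(sample$n_total >= 1)
  data.frame(upper = sample$intervals$upper,
             cum_prop = cumsum(sample$intervals$count) / sample$n_total)
}

#' Cumulative-distribution least-squares fit (CD-NLS)
#'
#' Fits the family by minimising the sum of squared differences between
#' the empirical cumulative proportions at the interval upper bounds
#' ([empirical_cumulative()]) and the candidate cdf evaluated there.
#' Needs at least three cumulative points; with fewer the fit is
#' reported as unconverged (the two-parameter problem is
#' under-determined), mirroring the non-convergence this method shows on
#' low-variance data.
#'
#' @inheritParams fit_bound_ml
#' @return A `fit_result` with `method = "cd_nls"`; `objective` is the
#'   residual sum of squares.
#' @export
fit_cd_nls <- function(sample, family = c("lognormal", "gamma", "weibull")) {
  family <- match.arg(family)
  check_sample(sample)
  ec <- empirical_cumulative(sample)
  if (nrow(ec) < 3L)
    return(fit_result(family, "cd_nls", n_used = nrow(ec)))

  rss <- function(p) {
    d <- try(retention_dist(family, p[1L], p[2L]), silent = TRUE)
    if (inherits(d, "try-error")) return(Inf)
    v <- sum((ec$cum_prop - pretention(d, ec$upper))^2)
    if (!is.finite(v)) Inf else v
  }
  start <- cd_start(sample, family)
  opt <- optimize_nat(rss, start, family)
  fit_result(family, "cd_nls", opt$par[1L], opt$par[2L],
             objective = opt$value, converged = opt$converged,
             n_used = nrow(ec))
}

#' Fit a censored sample with any of the five methods
#'
#' Dispatches to [fit_bound_ml()] (methods `"lower"`, `"mid"`,
#' `"upper"`), [fit_cd_ml()] or [fit_cd_nls()].
#'
#' @inheritParams fit_bound_ml
#' @param method Fitting method.
#' @return A `fit_result`.
#' @export
fit_retention <- function(sample,
                          family = c("lognormal", "gamma", "weibull"),
                          method = c("cd_ml", "cd_nls", "lower", "mid",
                                     "upper")) {
  method <- match.arg(method)
  family <- match.arg(family)
  switch(method,
         cd_ml  = fit_cd_ml(sample, family),
         cd_nls = fit_cd_nls(sample, family),
         fit_bound_ml(sample, family, bound = method))
}

#' The five fitting-method labels
#' @return Character vector of method names.
#' @export
fitting_methods <- function() c("lower", "mid", "upper", "cd_ml", "cd_nls")
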