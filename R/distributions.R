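#' Parametric retention-time distributions
#'
#' Constructor for the parametric families used to model propagule
#' retention time: lognormal, gamma and Weibull. Throughout the package a
#' distribution is described by a generic location/shape parameter `mu`
#' and a variance/scale parameter `sigma`, mapped onto the base-R
#' parameterizations as follows:
#'
#' * `lognormal`: `mu` = log-mean (`meanlog`), `sigma` = log-sd (`sdlog`);
#' * `gamma`: `mu` = shape, `sigma` = rate (1/hours);
#' * `weibull`: `mu` = shape, `sigma` = scale (hours).
#'
#' Time is measured in hours everywhere.
#'
#' @param family One of `"lognormal"`, `"gamma"`, `"weibull"`.
#' @param mu Location (lognormal) or shape (gamma, Weibull) parameter.
#'   Must be strictly positive for gamma and Weibull.
#' @param sigma Log-sd (lognormal), rate (gamma) or scale (Weibull)
#'   parameter; strictly positive.
#' @return An object of class `retention_dist` with fields `family`,
#'   `mu` and `sigma`.
#' @examples
#' d <- retention_dist("lognormal", mu = 1.8, sigma = 0.6)
#' pretention(d, 6)         # P(retention <= 6 h)
#' qretention(d, 0.5)       # median retention time, exp(1.8) hours
#' @export
retention_dist <- function(family = c("lognormal", "gamma", "weibull"),
                           mu, sigma) {
  family <- match.arg(family)
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0)
    stop("`sigma` must be strictly positive", call. = FALSE)
  if (family != "lognormal" && mu <= 0)
    stop("`mu` (shape) must be strictly positive for the ", family,
         " family", call. = FALSE)
  structure(list(family = family, mu = as.numeric(mu),
                 sigma = as.numeric(sigma)),
            class = "retention_dist")
}

#' @export
print.retention_dist <- function(x, ...) {
  cat(sprintf("<retention_dist> %s(mu = %g, sigma = %g)\n",
              x$family, x$mu, x$sigma))
  invisible(x)
}

is_retention_dist <- function(x) inherits(x, "retention_dist")

check_dist <- function(dist) {
  if (!is_retention_dist(dist))
    stop("expected a `retention_dist` object", call. = FALSE)
  dist
}

#' Density of a retention-time distribution
#'
#' @param dist A [retention_dist()] object.
#' @param t Times in hours, `t >= 0`.
#' @return Density values at `t`.
#' @export
dretention <- function(dist, t) {
  check_dist(dist)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  switch(dist$family,
         lognormal = stats::dlnorm(t, meanlog = dist$mu, sdlog = dist$sigma),
         gamma     = stats::dgamma(t, shape = dist$mu, rate = dist$sigma),
         weibull   = stats::dweibull(t, shape = dist$mu, scale = dist$sigma))
}

#' Cumulative probability of a retention-time distribution
#'
#' The probability that a propagule has been released by time `t`.
#'
#' @inheritParams dretention
#' @return Probabilities in `[0, 1]`, monotone in `t`.
#' @export
pretention <- function(dist, t) {
  check_dist(dist)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  switch(dist$family,
         lognormal = stats::plnorm(t, meanlog = dist$mu, sdlog = dist$sigma),
         gamma     = stats::pgamma(t, shape = dist$mu, rate = dist$sigma),
         weibull   = stats::pweibull(t, shape = dist$mu, scale = dist$sigma))
}

#' Quantiles of a retention-time distribution
#'
#' Inverse of [pretention()]: the time by which a proportion `p` of
#' propagules has been released.
#'
#' @inheritParams dretention
#' @param p Probabilities strictly inside `(0, 1)`.
#' @return Times in hours.
#' @export
qretention <- function(dist, p) {
  check_dist(dist)
  if (any(p <= 0 | p >= 1))
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  switch(dist$family,
         lognormal = stats::qlnorm(p, meanlog = dist$mu, sdlog = dist$sigma),
         gamma     = stats::qgamma(p, shape = dist$mu, rate = dist$sigma),
         weibull   = stats::qweibull(p, shape = dist$mu, scale = dist$sigma))
}

#' Random retention times
#'
#' Draws `n` independent retention times. When `seed` is given the draw
#' is reproducible and the caller's RNG state is left untouched.
#'
#' @inheritParams dretention
#' @param n Number of draws, `n >= 1`.
#' @param seed Optional integer seed.
#' @return A numeric vector of `n` strictly positive times (hours).
#' @export
rretention <- function(dist, n, seed = NULL) {
  check_dist(dist)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  with_seed(seed, switch(dist$family,
    lognormal = stats::rlnorm(n, meanlog = dist$mu, sdlog = dist$sigma),
    gamma     = stats::rgamma(n, shape = dist$mu, rate = dist$sigma),
    weibull   = stats::rweibull(n, shape = dist$mu, scale = dist$sigma)))
}

#' Serialize / deserialize a distribution as a three-field record
#'
#' `dist_record()` turns a [retention_dist()] into a one-row data frame
#' `(family, mu, sigma)` suitable for config files and CSV output;
#' `as_retention_dist()` is its inverse and also accepts a named list.
#'
#' @param dist A [retention_dist()] object.
#' @return `dist_record()`: a one-row `data.frame`; `as_retention_dist()`:
#'   a `retention_dist`.
#' @export
dist_record <- function(dist) {
  check_dist(dist)
  data.frame(family = dist$family, mu = dist$mu, sigma = dist$sigma,
             stringsAsFactors = FALSE)
}

#' @rdname dist_record
#' @param x A one-row data frame or named list with fields `family`,
#'   `mu`, `sigma`.
#' @export
as_retention_dist <- function(x) {
  if (is_retention_dist(x)) return(x)
  retention_dist(as.character(x$family), as.numeric(x$mu),
                 as.numeric(x$sigma))
}

# Run `code` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
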