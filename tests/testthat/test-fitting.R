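test_that("expand_to_points produces the chosen interval bound per count", {
  s <- toy_sample()   # (0,1]: 2, (1,2]: 1
  expect_equal(expand_to_points(s, "upper"), c(1, 1, 2))
  expect_equal(expand_to_points(s, "mid"), c(0.5, 0.5, 1.5))
  expect_equal(expand_to_points(s, "lower"), c(0.01, 0.01, 1))
  # right-censored propagules contribute no point
  s2 <- censored_sample(c(0, 1), c(1, 2), c(2, 1), right_censored = 4)
  expect_length(expand_to_points(s2, "mid"), 3)
})

test_that("lognormal bound ML matches its closed form", {
  s <- simulate_censored(default_retention_dist(), 300,
                         make_scheme("regular", width = 2), seed = 17)
  for (b in c("lower", "mid", "upper")) {
    fit <- fit_bound_ml(s, "lognormal", b)
    x <- expand_to_points(s, b)
    expect_true(fit$converged)
    expect_equal(fit$mu_hat, mean(log(x)), tolerance = 1e-6)
    expect_equal(fit$sigma_hat, sqrt(mean((log(x) - mean(log(x)))^2)),
                 tolerance = 1e-6)
    expect_equal(fit$objective, -sum(log(dretention(fitted_dist(fit), x))),
                 tolerance = 1e-8)
  }
})

test_that("bound ML on fine bins recovers Weibull parameters", {
  d <- retention_dist("weibull", 2, 10)
  x <- rretention(d, 1e5, seed = 31)
  sch <- make_scheme("breakpoints",
                     breakpoints = seq(0, ceiling(max(x)) + 1, by = 0.1))
  fit <- fit_bound_ml(bin_times(x, sch), "weibull", "mid")
  expect_true(fit$converged)
  expect_equal(fit$mu_hat, 2, tolerance = 0.02)
  expect_equal(fit$sigma_hat, 10, tolerance = 0.02)
})

test_that("upper-bound fits sit above lower-bound fits", {
  s <- simulate_censored(default_retention_dist(), 500,
                         make_scheme("regular", width = 4), seed = 13)
  up <- fit_bound_ml(s, "lognormal", "upper")
  lo <- fit_bound_ml(s, "lognormal", "lower")
  expect_gt(up$mu_hat, lo$mu_hat)
})

test_that("degenerate point data is reported as unconverged, not an error", {
  s <- censored_sample(0, 1, 5)   # all expanded points identical
  fit <- fit_bound_ml(s, "lognormal", "mid")
  expect_false(fit$converged)
  expect_true(is.na(fit$mu_hat))
})

test_that("censored_nll matches hand-computed values and contracts", {
  # exponential special case: one observed interval + one right-censored
  s <- censored_sample(0, 1, 1, right_censored = 1)
  nll <- censored_nll(c(1, 1), s, "gamma")
  expect_equal(nll, -log((1 - exp(-1)) * exp(-1)), tolerance = 1e-12)
  # total probability: a single interval covering the support gives NLL 0
  s_all <- censored_sample(0, 1e6, 7)
  for (fam in c("lognormal", "gamma", "weibull"))
    expect_equal(censored_nll(c(2, 1), s_all, fam), 0, tolerance = 1e-9)
  # linearity in counts
  s1 <- censored_sample(c(0, 2), c(2, 5), c(3, 4), right_censored = 2)
  s2 <- censored_sample(c(0, 2), c(2, 5), c(6, 8), right_censored = 4)
  expect_equal(censored_nll(c(1.5, 0.7), s2, "lognormal"),
               2 * censored_nll(c(1.5, 0.7), s1, "lognormal"))
  # +Inf contract: positive count in a zero-probability interval
  tight <- retention_dist("lognormal", 5, 0.01)
  far <- censored_sample(c(0, 1), c(1, 2), c(5, 5))
  expect_identical(censored_nll(c(5, 0.01), far, "lognormal"), Inf)
  expect_identical(censored_nll(c(1, -1), far, "lognormal"), Inf)
})

test_that("censored_nll is the multinomial log-likelihood up to a constant", {
  s <- simulate_censored(default_retention_dist(), 200,
                         make_scheme("regular", width = 4), seed = 21)
  cell_probs <- function(p) {
    d <- retention_dist("lognormal", p[1], p[2])
    c(diff(pretention(d, c(s$intervals$lower[1], s$intervals$upper))),
      1 - pretention(d, s$horizon))
  }
  counts <- c(s$intervals$count, s$right_censored)
  mn <- function(p) -dmultinom(counts, prob = cell_probs(p), log = TRUE)
  p1 <- c(1.8, 0.6); p2 <- c(2.1, 0.45)
  expect_equal(censored_nll(p1, s, "lognormal") -
                 censored_nll(p2, s, "lognormal"),
               mn(p1) - mn(p2), tolerance = 1e-8)
})

test_that("CD-ML matches a brute-force grid search on small fixtures", {
  fixtures <- list(
    list(dist = retention_dist("lognormal", 1.8, 0.6), n = 80, w = 4),
    list(dist = retention_dist("lognormal", 1.3, 0.9), n = 60, w = 2),
    list(dist = retention_dist("gamma", 2.5, 0.4), n = 80, w = 4),
    list(dist = retention_dist("gamma", 3.5, 0.8), n = 60, w = 2),
    list(dist = retention_dist("weibull", 1.8, 9), n = 80, w = 4)
  )
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    s <- simulate_censored(fx$dist, fx$n, make_scheme("regular", w = fx$w),
                           seed = 40 + i)
    fit <- fit_cd_ml(s, fx$dist$family)
    expect_true(fit$converged)
    # grid oracle: exhaustive search at step 0.005 around the truth
    step <- 0.005
    mu_grid <- seq(fx$dist$mu * 0.6, fx$dist$mu * 1.4, by = step)
    sg_grid <- seq(fx$dist$sigma * 0.6, fx$dist$sigma * 1.4, by = step)
    nll <- outer(mu_grid, sg_grid,
                 Vectorize(function(m, g) censored_nll(c(m, g), s,
                                                       fx$dist$family)))
    best <- arrayInd(which.min(nll), dim(nll))
    # the optimizer must beat the exhaustive grid ...
    expect_lte(fit$objective, min(nll) + 1e-6)
    # ... and land next to its argmin (two steps: the likelihood valley
    # is diagonal, so the grid argmin need not be the nearest node)
    expect_lt(abs(fit$mu_hat - mu_grid[best[1]]), 2 * step + 1e-9)
    expect_lt(abs(fit$sigma_hat - sg_grid[best[2]]), 2 * step + 1e-9)
    # the ML estimate beats the generating parameters
    expect_lte(fit$objective,
               censored_nll(c(fx$dist$mu, fx$dist$sigma), s,
                            fx$dist$family) + 1e-9)
  }
})

test_that("CD-ML recovers parameters from large finely-binned samples", {
  d <- default_retention_dist()
  s <- simulate_censored(d, 1e5, make_scheme("regular", width = 0.5),
                         seed = 53)
  fit <- fit_cd_ml(s, "lognormal")
  expect_true(fit$converged)
  expect_equal(fit$mu_hat, 1.8, tolerance = 0.01)
  expect_equal(fit$sigma_hat, 0.6, tolerance = 0.01)
})

test_that("CD-ML agrees with an independent censored-ML implementation", {
  skip_if_not_installed("fitdistrplus")
  s <- simulate_censored(default_retention_dist(), 400,
                         default_study_scheme(), seed = 61)
  fit <- fit_cd_ml(s, "lognormal")
  # fitdistrplus wants one (left, right) row per observation
  cens <- data.frame(left = rep(s$intervals$lower, s$intervals$count),
                     right = rep(s$intervals$upper, s$intervals$count))
  ref <- fitdistrplus::fitdistcens(cens, "lnorm")
  expect_equal(fit$mu_hat, unname(ref$estimate["meanlog"]),
               tolerance = 1e-4)
  expect_equal(fit$sigma_hat, unname(ref$estimate["sdlog"]),
               tolerance = 1e-4)
})

test_that("single-interval samples are unidentifiable and say so", {
  s <- censored_sample(0, 4, 50, right_censored = 0)
  expect_false(fit_cd_ml(s, "lognormal")$converged)
})

test_that("empirical cumulative proportions are running sums at uppers", {
  s <- censored_sample(c(0, 1, 2), c(1, 2, 4), c(5, 3, 2))
  ec <- empirical_cumulative(s)
  expect_equal(ec$upper, c(1, 2, 4))
  expect_equal(ec$cum_prop, c(0.5, 0.8, 1.0))
  # right-censored mass keeps the last point below 1
  s2 <- censored_sample(c(0, 1), c(1, 2), c(5, 3), right_censored = 2)
  expect_equal(empirical_cumulative(s2)$cum_prop, c(0.5, 0.8))
  # empty intervals carry the running value unchanged
  s3 <- censored_sample(c(0, 1, 2), c(1, 2, 3), c(4, 0, 4))
  expect_equal(empirical_cumulative(s3)$cum_prop, c(0.5, 0.5, 1.0))
})

test_that("CD-NLS has a zero-residual fixed point at the true cdf", {
  d <- default_retention_dist()
  # counts proportional to the exact interval masses of a huge sample,
  # so the empirical cumulative curve is numerically the true cdf
  bp <- 0:52
  counts <- round(diff(pretention(d, bp)) * 1e8)
  s <- censored_sample(bp[-length(bp)], bp[-1], counts,
                       right_censored = round((1 - pretention(d, 52)) * 1e8))
  fit <- fit_cd_nls(s, "lognormal")
  expect_true(fit$converged)
  expect_equal(fit$mu_hat, 1.8, tolerance = 1e-4)
  expect_equal(fit$sigma_hat, 0.6, tolerance = 1e-4)
  expect_lt(fit$objective, 1e-10)
})

test_that("CD-NLS matches a brute-force RSS grid search", {
  s <- simulate_censored(default_retention_dist(), 80,
                         make_scheme("regular", width = 4), seed = 71)
  fit <- fit_cd_nls(s, "lognormal")
  expect_true(fit$converged)
  ec <- empirical_cumulative(s)
  step <- 0.005
  mu_grid <- seq(1.2, 2.4, by = step)
  sg_grid <- seq(0.35, 0.95, by = step)
  rss <- outer(mu_grid, sg_grid, Vectorize(function(m, g)
    sum((ec$cum_prop -
           pretention(retention_dist("lognormal", m, g), ec$upper))^2)))
  best <- arrayInd(which.min(rss), dim(rss))
  expect_lt(abs(fit$mu_hat - mu_grid[best[1]]), step + 1e-9)
  expect_lt(abs(fit$sigma_hat - sg_grid[best[2]]), step + 1e-9)
})

test_that("CD-NLS refuses under-determined problems", {
  s <- censored_sample(c(0, 1), c(1, 2), c(5, 5))
  fit <- fit_cd_nls(s, "lognormal")
  expect_false(fit$converged)
})

test_that("all five methods agree on finely binned data", {
  d <- default_retention_dist()
  x <- rretention(d, 1e5, seed = 83)
  sch <- make_scheme("breakpoints",
                     breakpoints = seq(0, ceiling(max(x)) + 1, by = 0.05))
  s <- bin_times(x, sch)
  fits <- lapply(fitting_methods(), function(m)
    fit_retention(s, "lognormal", m))
  mus <- vapply(fits, `[[`, numeric(1), "mu_hat")
  sgs <- vapply(fits, `[[`, numeric(1), "sigma_hat")
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  expect_lt(diff(range(mus)) / mean(mus), 0.01)
  expect_lt(diff(range(sgs)) / mean(sgs), 0.01)
})

test_that("coarse mid-point binning overestimates the lognormal sigma", {
  d <- default_retention_dist()
  sch <- make_scheme("regular", width = 4)
  sig <- replicate(100, NA_real_)
  for (r in 1:100) {
    s <- simulate_censored(d, 500, sch, seed = 3000 + r)
    sig[r] <- fit_bound_ml(s, "lognormal", "mid")$sigma_hat
  }
  expect_gt(mean(sig), 0.6)
})

test_that("fitting is deterministic given the sample", {
  s <- simulate_censored(default_retention_dist(), 300,
                         default_study_scheme(), seed = 91)
  for (m in fitting_methods()) {
    f1 <- fit_retention(s, "lognormal", m)
    f2 <- fit_retention(s, "lognormal", m)
    expect_identical(f1, f2)
  }
})
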