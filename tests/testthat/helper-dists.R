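# One representative distribution per family, shapes typical of gut
# retention curves (unimodal, right-skewed, mode within a few hours).
example_dists <- function() {
  list(
    lognormal = retention_dist("lognormal", mu = 1.8, sigma = 0.6),
    gamma     = retention_dist("gamma", mu = 2.5, sigma = 0.4),
    weibull   = retention_dist("weibull", mu = 1.8, sigma = 9)
  )
}

# Small hand-buildable censored sample used by several fitting tests.
toy_sample <- function() {
  censored_sample(lower = c(0, 1), upper = c(1, 2), count = c(2, 1))
}
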