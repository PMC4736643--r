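#' Configuration for the simulation studies
#'
#' Bundles every knob of the benchmarking studies: which families and
#' fitting methods to compare, the Latin Hypercube design size, sample
#' sizes, collection schedules, replicate count, and the master seed
#' from which all per-replicate seeds are derived (so any study rerun
#' with the same config is reproducible byte for byte).
#'
#' The default collection schedule for the method-comparison and
#' sample-size studies is the mode-resolving mixed design: 1 h
#' intervals to 8 h, then 4 h intervals to 52 h.
#'
#' @param families Subset of `c("lognormal", "gamma", "weibull")`.
#' @param methods Subset of [fitting_methods()].
#' @param n_replicates Replicates per condition (default 100).
#' @param sample_size Propagules per simulated trial (default 500).
#' @param sample_sizes Grid for the sample-size study.
#' @param scheme Collection schedule for single-scheme studies.
#' @param schemes Named list of schedules for the interval study.
#' @param lhs_k Latin Hypercube design size per family (default 30).
#' @param lhs_ranges Optional per-family ranges, a named list of
#'   [default_lhs_ranges()]-shaped lists.
#' @param original Original distribution for the lognormal-only studies
#'   (default [default_retention_dist()]).
#' @param movement [movement_model()] for the kernel-bias study.
#' @param ks_n Resample size of the KS evaluation (default 500).
#' @param kernel_n Monte Carlo draws per kernel (default 1e5).
#' @param seed Master seed (default 1).
#' @param fast If `TRUE`, switch to the reduced profile (`lhs_k = 10`,
#'   `n_replicates = 20`) used for quick, lower-precision runs.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(families = c("lognormal", "gamma", "weibull"),
                              methods = fitting_methods(),
                              n_replicates = 100,
                              sample_size = 500,
                              sample_sizes = c(50, 100, 250, 500, 1000, 1500),
                              scheme = default_study_scheme(),
                              schemes = default_interval_schemes(),
                              lhs_k = 30,
                              lhs_ranges = NULL,
                              original = default_retention_dist(),
                              movement = movement_model("fixed_speed",
                                                        speed = 60),
                              ks_n = 500,
                              kernel_n = 1e5,
                              seed = 1,
                              fast = FALSE) {
  families <- match.arg(families, several.ok = TRUE)
  methods <- match.arg(methods, fitting_methods(), several.ok = TRUE)
  if (fast) {
    lhs_k <- 10
    n_replicates <- 20
  }
  stopifnot(n_replicates >= 1, sample_size >= 1, lhs_k >= 1,
            all(sample_sizes >= 1), ks_n >= 1, kernel_n >= 1)
  check_scheme(scheme)
  stopifnot(is.list(schemes), length(schemes) >= 1,
            !is.null(names(schemes)))
  lapply(schemes, check_scheme)
  check_dist(original)
  structure(list(families = families, methods = methods,
                 n_replicates = as.integer(n_replicates),
                 sample_size = as.integer(sample_size),
                 sample_sizes = as.integer(sample_sizes),
                 scheme = scheme, schemes = schemes,
                 lhs_k = as.integer(lhs_k), lhs_ranges = lhs_ranges,
                 original = original, movement = movement,
                 ks_n = as.integer(ks_n), kernel_n = as.integer(kernel_n),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Default collection schedule for the benchmarking studies
#'
#' 1 h intervals up to 8 h (resolving the mode), then 4 h intervals up
#' to the 52 h horizon.
#'
#' @return A [make_scheme()] object.
#' @export
default_study_scheme <- function() {
  make_scheme("tail_varied", tail_width = 4)
}

# Deterministic per-replicate seeds: sequential offsets from the master
# seed; KS seeds live in a distinct block so they never collide with
# simulation seeds within a study.
sim_seed <- function(config, idx) config$seed + idx
ks_seed <- function(config, idx, method_idx) {
  config$seed + 1000000L + (idx - 1L) * 10L + method_idx
}

# Fit one simulated sample with each configured method and evaluate it.
evaluate_methods <- function(samp, original, config, idx) {
  rows <- lapply(seq_along(config$methods), function(mi) {
    m <- config$methods[mi]
    fit <- fit_retention(samp, original$family, m)
    ks <- NA_real_
    kseed <- ks_seed(config, idx, mi)
    if (isTRUE(fit$converged))
      ks <- ks_sampled(fitted_dist(fit), original, n = config$ks_n,
                       seed = kseed)$statistic
    pd <- param_difference(fit, original)
    data.frame(method = m, mu_hat = fit$mu_hat, sigma_hat = fit$sigma_hat,
               converged = fit$converged, objective = fit$objective,
               ks = ks, mu_diff = unname(pd[1L]),
               sigma_diff = unname(pd[2L]), ks_seed = kseed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

run_replicates <- function(config, conditions, simulate_one) {
  idx <- 0L
  all_rows <- vector("list", nrow(conditions) * config$n_replicates)
  seeds_used <- integer(0)
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, , drop = FALSE]
    for (rep in seq_len(config$n_replicates)) {
      idx <- idx + 1L
      sseed <- sim_seed(config, idx)
      seeds_used <- c(seeds_used, sseed)
      rows <- tryCatch({
        out <- simulate_one(cond, sseed, idx)
        out$replicate <- rep
        out$sim_seed <- sseed
        cbind(cond[rep(1L, nrow(out)), , drop = FALSE], out,
              row.names = NULL)
      }, error = function(e) {
        warning(sprintf("replicate failed (condition %d, rep %d, seed %d): %s",
                        ci, rep, sseed, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
      all_rows[[idx]] <- rows
    }
  }
  stopifnot(!anyDuplicated(seeds_used))   # replicate seeds never collide
  res <- do.call(rbind, all_rows)
  rownames(res) <- NULL
  res
}

#' Method-comparison study across families and distribution shapes
#'
#' For each family, draws a Latin Hypercube design of original
#' parameters, simulates replicate interval-censored trials from each
#' original distribution (sample size and schedule from the config),
#' fits every configured method, and evaluates the sampled KS statistic
#' and the signed parameter errors against the original.
#'
#' @param config An [experiment_config()].
#' @return A list of class `retention_study` with `results` (one row
#'   per family x parameter set x replicate x method) and `summary`
#'   (means and standard errors per family x method, converged
#'   replicates only).
#' @export
run_method_comparison <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  conds <- do.call(rbind, lapply(seq_along(config$families), function(fi) {
    fam <- config$families[fi]
    ranges <- config$lhs_ranges[[fam]]
    sets <- lhs_parameter_sets(fam, ranges = ranges, k = config$lhs_k,
                               seed = config$seed + 900000L + fi)
    sets$set_id <- seq_len(nrow(sets))
    sets
  }))
  names(conds)[names(conds) == "mu"] <- "mu_true"
  names(conds)[names(conds) == "sigma"] <- "sigma_true"

  results <- run_replicates(config, conds, function(cond, sseed, idx) {
    orig <- retention_dist(cond$family, cond$mu_true, cond$sigma_true)
    samp <- simulate_censored(orig, config$sample_size, config$scheme,
                              seed = sseed)
    evaluate_methods(samp, orig, config, idx)
  })
  new_study("method_comparison", results,
            aggregate_replicates(results, by = c("family", "method")))
}

#' Sample-size robustness study
#'
#' Simulates trials from a single lognormal original distribution at a
#' grid of sample sizes (number of retrieved propagules), fits every
#' configured method, and summarises accuracy per sample size and
#' method.
#'
#' @inheritParams run_method_comparison
#' @return A `retention_study`; `results` carry a `sample_size` column
#'   and `condition` labels `"N50"`, `"N100"`, ...
#' @export
run_sample_size_study <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  orig <- config$original
  conds <- data.frame(condition = paste0("N", config$sample_sizes),
                      sample_size = config$sample_sizes,
                      family = orig$family, stringsAsFactors = FALSE)
  results <- run_replicates(config, conds, function(cond, sseed, idx) {
    samp <- simulate_censored(orig, cond$sample_size, config$scheme,
                              seed = sseed)
    evaluate_methods(samp, orig, config, idx)
  })
  new_study("sample_size", results,
            aggregate_replicates(results, by = c("condition", "method")))
}

#' Sampling-interval robustness study
#'
#' Simulates trials from a single lognormal original distribution at a
#' fixed sample size, binned under each configured collection schedule
#' (by default the ten canonical schemes of
#' [default_interval_schemes()]), fits every configured method, and
#' summarises accuracy per scheme and method.
#'
#' @inheritParams run_method_comparison
#' @return A `retention_study`; `results` carry a `condition` column
#'   naming the scheme.
#' @export
run_interval_study <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  orig <- config$original
  conds <- data.frame(condition = names(config$schemes),
                      family = orig$family, stringsAsFactors = FALSE)
  results <- run_replicates(config, conds, function(cond, sseed, idx) {
    samp <- simulate_censored(orig, config$sample_size,
                              config$schemes[[cond$condition]],
                              seed = sseed)
    evaluate_methods(samp, orig, config, idx)
  })
  new_study("interval_scheme", results,
            aggregate_replicates(results, by = c("condition", "method")))
}

#' Kernel-bias study
#'
#' For each scenario (a named collection schedule), simulates one
#' censored trial from the original distribution, fits it with every
#' configured method, estimates the dispersal kernel implied by each
#' converged fit under the configured movement model, and tabulates the
#' percent bias of each method's kernel statistics relative to CD-ML.
#'
#' @inheritParams run_method_comparison
#' @param scenarios Named list of [make_scheme()] objects; defaults to a
#'   coarse (regular 4 h) and a fine (regular 1 h) schedule.
#' @return A data frame with one row per scenario x method: the four
#'   kernel statistics and their percent biases versus CD-ML
#'   (reference rows carry missing biases).
#' @export
run_kernel_bias <- function(config = experiment_config(),
                            scenarios = list(
                              coarse_4h = make_scheme("regular", width = 4),
                              fine_1h = make_scheme("regular", width = 1))) {
  stopifnot(inherits(config, "experiment_config"))
  lapply(scenarios, check_scheme)
  orig <- config$original
  methods <- union("cd_ml", config$methods)
  out <- lapply(seq_along(scenarios), function(si) {
    samp <- simulate_censored(orig, config$sample_size,
                              scenarios[[si]],
                              seed = config$seed + 500000L + si)
    summaries <- stats::setNames(lapply(seq_along(methods), function(mi) {
      fit <- fit_retention(samp, orig$family, methods[mi])
      if (!isTRUE(fit$converged)) return(NULL)
      estimate_kernel(fitted_dist(fit), config$movement,
                      n = config$kernel_n,
                      seed = config$seed + 600000L + si * 100L + mi)
    }), methods)
    tab <- bias_table(summaries, reference = "cd_ml")
    cbind(data.frame(scenario = names(scenarios)[si],
                     stringsAsFactors = FALSE), tab, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

new_study <- function(study, results, summary) {
  structure(list(study = study, results = results, summary = summary),
            class = "retention_study")
}

#' @export
print.retention_study <- function(x, ...) {
  cat(sprintf("<retention_study> %s: %d replicate rows, %d summary rows\n",
              x$study, nrow(x$results), nrow(x$summary)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a study's tidy and summary tables to CSV
#'
#' Writes `<study>_results.csv` (one row per replicate x method) and
#' `<study>_summary.csv` into `dir`. Rerunning a study with the same
#' config and master seed reproduces both files byte for byte.
#'
#' @param study A `retention_study`.
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "retention_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(study$study,
                                 c("_results.csv", "_summary.csv")))
  utils::write.csv(study$results, paths[1L], row.names = FALSE)
  utils::write.csv(study$summary, paths[2L], row.names = FALSE)
  invisible(paths)
}
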