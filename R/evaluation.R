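#' Empirical mean squared error of estimated marginal trajectories
#'
#' Replicate-averaged squared deviation of the estimated marginal mean
#' from the generating truth at each grid time:
#' \deqn{MSE(t) = \frac{1}{R} \sum_{r=1}^R (Y(t) - \hat Y_r(t))^2.}
#'
#' @param true_curve numeric vector, the generating marginal mean on the
#'   evaluation grid.
#' @param estimated_curves numeric matrix with one row per replicate and
#'   one column per grid time (a single replicate may be given as a
#'   vector).
#' @return numeric vector of per-time MSE values.
#' @export
empirical_mse <- function(true_curve, estimated_curves) {
  if (!is.matrix(estimated_curves)) {
    estimated_curves <- matrix(estimated_curves, nrow = 1L)
  }
  if (ncol(estimated_curves) != length(true_curve)) {
    stop("empirical_mse: estimated curves and truth use different grids")
  }
  dev <- sweep(estimated_curves, 2L, true_curve, "-")
  colMeans(dev * dev)
}

#' Percent bias of the average estimated marginal trajectory
#'
#' `100 * |mean_r(Yhat_r(t)) - Y(t)| / |Y(t)|` per grid time; times where
#' the truth is numerically zero (|Y(t)| < 1e-6) are masked with `NA`.
#'
#' @inheritParams empirical_mse
#' @return numeric vector of percent bias values.
#' @export
percent_bias <- function(true_curve, estimated_curves) {
  if (!is.matrix(estimated_curves)) {
    estimated_curves <- matrix(estimated_curves, nrow = 1L)
  }
  if (ncol(estimated_curves) != length(true_curve)) {
    stop("percent_bias: estimated curves and truth use different grids")
  }
  out <- 100 * abs(colMeans(estimated_curves) - true_curve) / abs(true_curve)
  out[abs(true_curve) < 1e-6] <- NA_real_
  out
}

#' Scenario grid of the full performance study
#'
#' The complete factorial grid (three sample sizes by three covariate
#' counts, one model family) intended for 100-replicate batch runs via
#' [run_simulation_study()]. It is provided for completeness and is far
#' larger than the desk-scale defaults used in the test-suite
#' replications.
#'
#' @param family model family.
#' @return data.frame with columns `family`, `n_subjects`,
#'   `n_covariates`.
#' @export
full_performance_grid <- function(family = "smm") {
  expand.grid(family = family, n_subjects = c(100L, 200L, 500L),
              n_covariates = 0:2, stringsAsFactors = FALSE)
}

#' Replicate the simulation performance study
#'
#' For each scenario (model family, sample size, covariates per parameter)
#' and each replicate: generate a dataset from the scenario's design,
#' compute starting values (automatic data-driven initials or the naive
#' all-zero comparison arm), fit the model by SAEM, and evaluate the
#' estimated marginal mean on a yearly grid. Aggregates the empirical
#' `MSE(t)`, the percent bias, the smoothing-phase convergence rate and
#' the mean runtime. A failed replicate fit is recorded, not fatal.
#'
#' @param scenarios data.frame with columns `family`, `n_subjects`,
#'   `n_covariates` (defaults to the desk-scale single scenario: `"smm"`,
#'   100 subjects, no covariates); see [full_performance_grid()] for the
#'   complete grid.
#' @param R replicates per scenario.
#' @param initials `"automatic"` (data-driven starting values) or
#'   `"naive_zero"` (all four main starts at zero).
#' @param seed integer; replicate r of scenario s uses seed
#'   `seed + 1000 * s + r` for both data generation and fitting.
#' @param control a [saem_control()] shared by all fits (its seed is
#'   overridden per replicate).
#' @param truth optional [pop_params()] overriding the generating
#'   parameters of every scenario (default: [default_truth()] per
#'   scenario).
#' @param out_dir optional directory where tidy per-replicate results and
#'   the summary are written as CSV.
#' @return an object of class `trajmix_simstudy`: list with `results`
#'   (scenario, replicate, year, truth, estimate), `summary` (per
#'   scenario and year: MSE, percent bias), `scenarios` (with convergence
#'   rate and mean runtime) and `failures`.
#' @export
run_simulation_study <- function(scenarios = NULL, R = 20L,
                                 initials = c("automatic", "naive_zero"),
                                 seed = 1L, control = saem_control(),
                                 truth = NULL, out_dir = NULL) {
  initials <- match.arg(initials)
  if (is.null(scenarios)) {
    scenarios <- data.frame(family = "smm", n_subjects = 100L,
                            n_covariates = 0L, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("family", "n_subjects", "n_covariates") %in%
                  names(scenarios)), R >= 1L)
  results <- list()
  scen_rows <- list()
  failures <- list()
  for (s in seq_len(nrow(scenarios))) {
    family <- as.character(scenarios$family[s])
    design <- simulation_design(
      n_subjects = scenarios$n_subjects[s], family = family,
      n_covariates = scenarios$n_covariates[s], truth = truth
    )
    years <- seq(design$window[1L], design$window[2L], by = 1)
    prof <- if (design$n_covariates > 0L) {
      rep(0, design$n_covariates)   # generating covariate mean
    } else NULL
    truth_curve <- pop_curve(design$truth, years, profile = prof,
                             v = design$v)
    spec <- model_spec(family,
                       var_all = if (design$n_covariates > 0L)
                         paste0("X", seq_len(design$n_covariates))
                       else character(),
                       v = design$v)
    conv <- logical(0)
    runtime <- numeric(0)
    for (r in seq_len(R)) {
      rseed <- seed + 1000L * s + r
      sim <- generate_simulation_dataset(design, seed = rseed)
      ctrl <- control
      ctrl$seed <- rseed
      start <- if (initials == "naive_zero") rep(0, 4L) else NULL
      fit <- tryCatch(
        suppressWarnings(saem_fit(spec, sim$data, start = start,
                                  control = ctrl)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(scenario = s, replicate = r,
                     message = conditionMessage(fit))
        next
      }
      est_curve <- pop_curve(estimated_params(fit), years, profile = prof,
                             v = design$v)
      conv <- c(conv, fit$converged_phase2)
      runtime <- c(runtime, fit$runtime_seconds)
      results[[length(results) + 1L]] <- data.frame(
        scenario = s, family = family,
        n_subjects = scenarios$n_subjects[s],
        n_covariates = scenarios$n_covariates[s],
        replicate = r, year = years, truth = truth_curve,
        estimate = est_curve, converged = fit$converged_phase2)
    }
    scen_rows[[s]] <- data.frame(
      scenario = s, family = family,
      n_subjects = scenarios$n_subjects[s],
      n_covariates = scenarios$n_covariates[s],
      replicates_done = length(conv),
      convergence_rate = if (length(conv)) mean(conv) else NA_real_,
      mean_runtime = if (length(runtime)) mean(runtime) else NA_real_)
  }
  results <- do.call(rbind, results)
  summ <- do.call(rbind, lapply(unique(results$scenario), function(s) {
    sub <- results[results$scenario == s, ]
    years <- sort(unique(sub$year))
    est <- t(vapply(unique(sub$replicate), function(r) {
      sr <- sub[sub$replicate == r, ]
      sr$estimate[order(sr$year)]
    }, numeric(length(years))))
    truth <- sub$truth[match(years, sub$year)]
    data.frame(scenario = s, year = years,
               mse = empirical_mse(truth, est),
               percent_bias = percent_bias(truth, est))
  }))
  out <- structure(list(results = results, summary = summ,
                        scenarios = do.call(rbind, scen_rows),
                        failures = if (length(failures))
                          do.call(rbind, failures) else NULL,
                        initials = initials, R = R, seed = seed),
                   class = "trajmix_simstudy")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.trajmix_simstudy <- function(x, ...) {
  cat("Simulation study (", x$R, " replicates per scenario, ",
      x$initials, " initials)\n", sep = "")
  for (s in seq_len(nrow(x$scenarios))) {
    sc <- x$scenarios[s, ]
    sub <- x$summary[x$summary$scenario == s, ]
    cat(sprintf(
      "  %s, N=%d, %d covariate(s): max MSE(t)=%.4g, mean MSE=%.4g, convergence %.0f%%\n",
      sc$family, sc$n_subjects, sc$n_covariates,
      max(sub$mse), mean(sub$mse), 100 * sc$convergence_rate))
  }
  if (!is.null(x$failures)) {
    cat("  failed replicates:", nrow(x$failures), "\n")
  }
  invisible(x)
}
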