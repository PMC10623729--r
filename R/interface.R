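#' Fit the sigmoidal mixed model
#'
#' High-level interface: reads or accepts a long-format dataset, builds
#' the model specification, computes automatic starting values (unless
#' overridden), runs the SAEM fit, and attaches standard errors, Wald
#' p-values, log-likelihoods and (optionally) estimated marginal
#' trajectories. Only the dataset and the identifier, outcome and time
#' column names are mandatory.
#'
#' @param dataset a data.frame in long format, or the path of a CSV file.
#' @param ID,outcome,time column names of the subject identifier, the
#'   longitudinal outcome and the timescale (which may be negative, e.g.
#'   years before death).
#' @param var_all covariate name(s) attached to all four structural
#'   parameters.
#' @param var_first_level,var_last_level,var_midpoint,var_hill_slope
#'   covariate name(s) attached to the corresponding parameter only.
#' @param traj_marg logical: compute the estimated marginal trajectory for
#'   the most common covariate profile.
#' @param traj_marg_group covariate name whose groups should be
#'   contrasted (binary: its two levels; continuous: percentiles).
#' @param traj_marg_group_val percentile pair for a continuous grouping
#'   covariate (default 10th and 90th).
#' @param start optional numeric vector of length 4 overriding the four
#'   main starting values element-wise (`NA` keeps the automatic value).
#' @param control a [saem_control()].
#' @param seed convenience override of `control$seed`.
#' @return an object of class `trajmix_fit` (see [saem_fit()]); marginal
#'   trajectories, when requested, are attached as `$marginal` and
#'   `$marginal_group`.
#' @export
fit_smm <- function(dataset, ID = "ID", outcome, time,
                    var_all = NULL, var_first_level = NULL,
                    var_last_level = NULL, var_midpoint = NULL,
                    var_hill_slope = NULL,
                    traj_marg = FALSE, traj_marg_group = NULL,
                    traj_marg_group_val = c(0.1, 0.9),
                    start = NULL, control = saem_control(), seed = NULL) {
  covs <- list(first.level = var_first_level, last.level = var_last_level,
               midpoint = var_midpoint, hill.slope = var_hill_slope)
  fit_frontend("smm", dataset, ID, outcome, time, covs, var_all, 0,
               traj_marg, traj_marg_group, traj_marg_group_val,
               start, control, seed)
}

#' Fit the piecewise mixed model with abrupt change
#'
#' @inheritParams fit_smm
#' @param var_slope1,var_slope2,var_changepoint covariate name(s) for the
#'   early slope, the late slope (the segment containing time 0) and the
#'   changepoint time.
#' @return an object of class `trajmix_fit`.
#' @export
fit_pmm_abrupt <- function(dataset, ID = "ID", outcome, time,
                           var_all = NULL, var_last_level = NULL,
                           var_slope1 = NULL, var_slope2 = NULL,
                           var_changepoint = NULL,
                           traj_marg = FALSE, traj_marg_group = NULL,
                           traj_marg_group_val = c(0.1, 0.9),
                           start = NULL, control = saem_control(),
                           seed = NULL) {
  covs <- list(last.level = var_last_level, slope2 = var_slope2,
               slope1 = var_slope1, changepoint = var_changepoint)
  fit_frontend("pmm_abrupt", dataset, ID, outcome, time, covs, var_all, 0,
               traj_marg, traj_marg_group, traj_marg_group_val,
               start, control, seed)
}

#' Fit the piecewise mixed model with smooth polynomial transition
#'
#' @inheritParams fit_pmm_abrupt
#' @param v fixed transition length in time units (default 2; `v = 0`
#'   reduces to the abrupt model).
#' @return an object of class `trajmix_fit`.
#' @export
fit_pmm_smooth <- function(dataset, ID = "ID", outcome, time,
                           var_all = NULL, var_last_level = NULL,
                           var_slope1 = NULL, var_slope2 = NULL,
                           var_changepoint = NULL, v = 2,
                           traj_marg = FALSE, traj_marg_group = NULL,
                           traj_marg_group_val = c(0.1, 0.9),
                           start = NULL, control = saem_control(),
                           seed = NULL) {
  covs <- list(last.level = var_last_level, slope2 = var_slope2,
               slope1 = var_slope1, changepoint = var_changepoint)
  fit_frontend("pmm_smooth", dataset, ID, outcome, time, covs, var_all, v,
               traj_marg, traj_marg_group, traj_marg_group_val,
               start, control, seed)
}

fit_frontend <- function(family, dataset, ID, outcome, time, covs, var_all,
                         v, traj_marg, traj_marg_group, traj_marg_group_val,
                         start, control, seed) {
  if (!is.null(start) &&
      (!is.numeric(start) || length(start) != 4L)) {
    stop("start must be a numeric vector of length 4")
  }
  if (!is.null(seed)) control$seed <- as.integer(seed)
  all_covs <- unique(c(var_all, unlist(covs)))
  data <- if (is.character(dataset)) {
    read_long_csv(dataset, id = ID, outcome = outcome, time = time,
                  covariates = all_covs)
  } else {
    long_data(dataset, id = ID, outcome = outcome, time = time,
              covariates = all_covs)
  }
  covs <- lapply(covs, function(x) as.character(x %||% character()))
  spec <- model_spec(family, covariates = covs,
                     var_all = as.character(var_all %||% character()),
                     v = v)
  fit <- saem_fit(spec, data, start = start, control = control)
  if (isTRUE(traj_marg)) {
    fit$marginal <- marginal_trajectory(fit)
  }
  if (!is.null(traj_marg_group)) {
    fit$marginal_group <- marginal_trajectory(
      fit, group = traj_marg_group, group_probs = traj_marg_group_val)
  }
  fit
}

#' @export
print.trajmix_fit <- function(x, digits = 4, ...) {
  pp <- x$prep
  cat("----------------------------------------------------\n")
  cat(family_name(pp$family), "fitted by SAEM\n")
  cat("----------------------------------------------------\n")
  cat("Data: ", pp$N, " subjects, ", pp$n_obs, " observations (",
      sprintf("%.1f", pp$n_obs / pp$N), " per subject on average)\n",
      sep = "")
  cat("  time range [", format(min(pp$t), digits = 3), ", ",
      format(max(pp$t), digits = 3), "]\n", sep = "")
  cat("\nModel:\n")
  for (k in 1:4) {
    cv <- x$spec$covariates[[k]]
    cat(sprintf("  %-12s ~ %s\n", pp$labels[k],
                if (length(cv)) paste(cv, collapse = " + ") else "1"))
  }
  if (pp$family == "pmm_smooth") {
    cat("  transition length v =", x$spec$v, "\n")
  }
  d <- length(pp$re_idx)
  cat("  random effects on: ",
      paste(pp$labels[pp$re_idx], collapse = ", "),
      if (pp$family == "smm") " (correlated)\n" else
        " (independent except slope2-slope1)\n", sep = "")
  cat("\nInitial values (provenance):\n")
  for (k in 1:4) {
    cat(sprintf("  %-12s %10.4g   [%s]\n", names(x$start$values)[k],
                x$start$values[k], x$start$provenance[k]))
  }
  cat("\nAlgorithm: SAEM, ", x$control$K1, " exploration + ",
      x$control$K2, " smoothing iterations, ", x$n_chains,
      " chain(s), seed ", x$seed, "\n", sep = "")
  cat("  smoothing phase stabilized:",
      if (x$converged_phase2) "yes" else "NO (see warnings)", "\n")
  cat("\nEstimates:\n")
  tab <- x$estimates
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$z <- signif(tab$z, digits)
  tab$p <- ifelse(is.na(tab$p), NA,
                  ifelse(tab$p < 1e-4, "<1e-04", signif(tab$p, 2)))
  print(tab, row.names = FALSE)
  cat("\nLog-likelihood (linearization):   ",
      format(x$loglik_linearization, digits = 8), "\n")
  if (is.finite(x$loglik_importance_sampling %||% NA)) {
    cat("Log-likelihood (importance sampl.):",
        format(x$loglik_importance_sampling, digits = 8), "\n")
  }
  cat("AIC:", format(x$AIC, digits = 8), "  BIC:",
      format(x$BIC, digits = 8), "\n")
  cat("Processing time:", sprintf("%.1f s", x$runtime_seconds), "\n")
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    for (w in unique(x$warnings)) cat("  -", w, "\n")
  }
  invisible(x)
}

#' @export
summary.trajmix_fit <- function(object, ...) {
  print(object, ...)
}

#' Inspect a longitudinal outcome before modelling
#'
#' Three diagnostic displays: the distribution of the outcome, a
#' spaghetti plot of the observed trajectories of a seeded random
#' subsample of subjects, and per-year boxplots of the observed measures
#' (integer-year time bins).
#'
#' @param dataset data.frame or CSV path.
#' @param ID,outcome,time column names.
#' @param sample_size subjects drawn for the spaghetti plot (default 70;
#'   clamped to the number of subjects).
#' @param xlabel,ylabel axis labels.
#' @param seed seed for the subsample.
#' @param out_dir optional directory where the figures are written as PNG.
#' @return list with ggplot objects `histogram`, `spaghetti`, `boxplots`
#'   and the `sampled_ids` used in the spaghetti plot.
#' @export
inspect_longitudinal <- function(dataset, ID = "ID", outcome, time,
                                 sample_size = 70L, xlabel = NULL,
                                 ylabel = NULL, seed = 1L, out_dir = NULL) {
  data <- if (is.character(dataset)) {
    read_long_csv(dataset, id = ID, outcome = outcome, time = time)
  } else if (inherits(dataset, "long_data")) {
    dataset
  } else {
    long_data(dataset, id = ID, outcome = outcome, time = time)
  }
  xlabel <- xlabel %||% attr(data, "time_col")
  ylabel <- ylabel %||% attr(data, "outcome_col")
  ids <- unique(data$id)
  set.seed(seed)
  n_draw <- min(sample_size, length(ids))
  if (n_draw < sample_size) {
    message("inspect_longitudinal: only ", n_draw,
            " subjects available; using all of them")
  }
  sampled <- sample(ids, n_draw)
  df <- as.data.frame(data)
  hist_plot <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::labs(x = ylabel, y = "count") +
    ggplot2::theme_minimal()
  spag <- ggplot2::ggplot(df[df$id %in% sampled, ],
                          ggplot2::aes(x = .data$time, y = .data$y,
                                       group = .data$id)) +
    ggplot2::geom_line(alpha = 0.5, colour = "grey25") +
    ggplot2::labs(x = xlabel, y = ylabel) +
    ggplot2::theme_minimal()
  df$year_bin <- factor(round(df$time))
  box <- ggplot2::ggplot(df, ggplot2::aes(x = .data$year_bin, y = .data$y)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey80") +
    ggplot2::labs(x = xlabel, y = ylabel) +
    ggplot2::theme_minimal()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ggplot2::ggsave(file.path(out_dir, "outcome_distribution.png"),
                    hist_plot, width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "spaghetti.png"), spag,
                    width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "yearly_boxplots.png"), box,
                    width = 7, height = 4, dpi = 150)
  }
  list(histogram = hist_plot, spaghetti = spag, boxplots = box,
       sampled_ids = sampled)
}

#' Convergence plot of a SAEM fit
#'
#' One panel per estimated parameter showing the estimate against the
#' iteration number, with the boundary between the exploration and
#' smoothing phases marked.
#'
#' @param fit a `trajmix_fit`.
#' @param parameters optional subset of trace column names.
#' @return a ggplot object.
#' @export
convergence_plot <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "trajmix_fit"))
  tr <- fit$trace
  if (!is.null(parameters)) tr <- tr[, parameters, drop = FALSE]
  df <- data.frame(
    iteration = rep(seq_len(nrow(tr)), ncol(tr)),
    parameter = factor(rep(colnames(tr), each = nrow(tr)),
                       levels = colnames(tr)),
    value = as.vector(tr)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::geom_vline(xintercept = fit$control$K1, linetype = 2,
                        colour = "red3") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "estimate") +
    ggplot2::theme_minimal()
}

#' @export
plot.trajmix_fit <- function(x, type = c("convergence", "marginal"), ...) {
  type <- match.arg(type)
  if (type == "convergence") return(convergence_plot(x))
  mg <- x$marginal_group %||% x$marginal %||% marginal_trajectory(x)
  aes <- if ("group" %in% names(mg)) {
    ggplot2::aes(x = .data$time, y = .data$value, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$time, y = .data$value)
  }
  ggplot2::ggplot(mg, aes) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = attr(x$data, "time_col"),
                  y = attr(x$data, "outcome_col")) +
    ggplot2::theme_minimal()
}

#' Write a plain-text report and a machine-readable estimates table
#'
#' @param fit a `trajmix_fit`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fit_report <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(utils::capture.output(print(fit)),
             file.path(dir, "report.txt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(fit$estimates, file.path(dir, "estimates.json"),
                         dataframe = "rows", digits = NA, na = "null")
  } else {
    utils::write.csv(fit$estimates, file.path(dir, "estimates.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
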