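# marginal curve of a population-parameter object at zero random effects,
# for a covariate profile given per structural parameter
pop_curve <- function(pop, times, profile = NULL, v = 0) {
  X <- if (is.null(profile)) NULL else {
    lapply(1:4, function(k) {
      bk <- pop$beta[[k]]
      if (!length(bk)) return(numeric())
      if (length(profile) < length(bk)) {
        stop("profile shorter than the coefficient vector of parameter ", k)
      }
      as.numeric(profile[seq_along(bk)])
    })
  }
  psi <- individual_parameters(pop, X = X, eta = NULL)
  structural_mean(pop$family, times,
                  matrix(psi, length(times), 4L, byrow = TRUE), v)
}

# most common value of a subject-level covariate; continuous covariates
# without repeats fall back to the median
common_value <- function(x) {
  tab <- table(x)
  if (max(tab) > 1L) {
    as.numeric(names(tab)[which.max(tab)])
  } else {
    stats::median(x)
  }
}

# subject-level covariate values (first row per subject)
subject_covariates <- function(fit) {
  pp <- fit$prep
  cvs <- unique(unlist(fit$spec$covariates))
  if (!length(cvs)) return(NULL)
  first_row <- match(pp$ids, fit$data$id)
  out <- lapply(cvs, function(cv) fit$data[[cv]][first_row])
  names(out) <- cvs
  as.data.frame(out)
}

#' Estimated marginal trajectory
#'
#' Evaluates the fitted structural mean at zero random effects for a fixed
#' covariate profile (by default the most common value of every covariate
#' in the model), optionally contrasted between two groups defined by one
#' covariate: for a binary covariate its two levels, for a continuous one
#' its 10th and 90th percentiles (overridable via `group_probs`), with all
#' other covariates held at the default profile.
#'
#' @param fit a `trajmix_fit`.
#' @param times numeric grid; defaults to 100 points spanning the observed
#'   times.
#' @param profile named numeric vector of covariate values; must cover
#'   every model covariate when supplied.
#' @param group name of the covariate defining the contrast (optional).
#' @param group_probs percentile pair for a continuous grouping covariate.
#' @return a data.frame with columns `time`, `value` and (for contrasts)
#'   `group`.
#' @export
marginal_trajectory <- function(fit, times = NULL, profile = NULL,
                                group = NULL, group_probs = c(0.1, 0.9)) {
  stopifnot(inherits(fit, "trajmix_fit"))
  pp <- fit$prep
  if (is.null(times)) {
    times <- seq(min(pp$t), max(pp$t), length.out = 100L)
  }
  cvs <- unique(unlist(fit$spec$covariates))
  sc <- subject_covariates(fit)
  if (is.null(profile)) {
    profile <- vapply(cvs, function(cv) common_value(sc[[cv]]), numeric(1L))
    names(profile) <- cvs
  } else {
    missing_cv <- setdiff(cvs, names(profile))
    if (length(missing_cv)) {
      stop("profile is missing covariate(s): ",
           paste(missing_cv, collapse = ", "))
    }
  }
  pop <- estimated_params(fit)
  curve_at <- function(prof) {
    X <- lapply(1:4, function(k) {
      cvk <- fit$spec$covariates[[k]]
      if (!length(cvk)) numeric() else as.numeric(prof[cvk])
    })
    psi <- individual_parameters(pop, X = X, eta = NULL)
    f_eval_engine(pp, times, matrix(psi, length(times), 4L, byrow = TRUE))
  }
  if (is.null(group)) {
    return(data.frame(time = times, value = curve_at(profile)))
  }
  if (!group %in% cvs) {
    stop("grouping covariate '", group, "' is not in the model")
  }
  gv <- sc[[group]]
  lv <- if (length(unique(gv)) == 2L) {
    sort(unique(gv))
  } else {
    stats::quantile(gv, group_probs, names = FALSE)
  }
  out <- lapply(seq_along(lv), function(g) {
    prof <- profile
    prof[group] <- lv[g]
    data.frame(time = times, value = curve_at(prof),
               group = sprintf("%s=%.4g", group, lv[g]))
  })
  do.call(rbind, out)
}

#' Subject-specific predictions
#'
#' Conditional random-effect estimates (posterior means from the final
#' smoothing-phase draws), the implied person-specific parameters, and
#' fitted values at the subject's observation times.
#'
#' @param fit a `trajmix_fit`.
#' @param subjects identifiers to extract (default: all).
#' @return a list with `eta` (subjects x random effects), `psi`
#'   (subjects x 4) and `observations` (id, time, observed, fitted,
#'   residual).
#' @export
predict_individual <- function(fit, subjects = NULL) {
  stopifnot(inherits(fit, "trajmix_fit"))
  pp <- fit$prep
  if (is.null(subjects)) subjects <- pp$ids
  pos <- match(subjects, pp$ids)
  if (any(is.na(pos))) {
    stop("unknown subject id(s): ",
         paste(subjects[is.na(pos)], collapse = ", "))
  }
  keep <- pp$subj %in% pos
  obs <- data.frame(id = fit$data$id[keep], time = pp$t[keep],
                    observed = pp$y[keep], fitted = fit$fitted[keep])
  obs$residual <- obs$observed - obs$fitted
  list(eta = fit$eta_hat[pos, , drop = FALSE],
       psi = fit$psi_hat[pos, , drop = FALSE],
       observations = obs)
}

#' Per-observation fitted values
#' @param fit a `trajmix_fit`.
#' @return data.frame with id, time, observed, fitted and residual.
#' @export
fitted_table <- function(fit) {
  predict_individual(fit)$observations
}
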