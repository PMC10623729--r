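#' Default generating parameters for each model family
#'
#' Population parameters used by the packaged generators and the
#' performance harness. They emulate composite global-cognition trajectories
#' of a cohort followed annually until death (death-anchored time, outcome
#' around 0.45 two decades before death and below 0 near death): a
#' sigmoidal decline with midpoint about 4 years before death, or a
#' piecewise decline with a gentle preterminal slope, a changepoint about
#' 3.5 years before death and a steep terminal slope. When covariates are
#' requested, fixed coefficients of modest size (relative to each
#' parameter's scale) are attached to every structural parameter.
#'
#' @param family model family string.
#' @param n_covariates number of (standard-normal, subject-level)
#'   covariates per structural parameter: 0, 1 or 2.
#' @return a [pop_params()] object.
#' @export
default_truth <- function(family = c("smm", "pmm_abrupt", "pmm_smooth"),
                          n_covariates = 0L) {
  family <- match.arg(family)
  stopifnot(n_covariates %in% 0:2)
  if (family == "smm") {
    alpha <- c(0.45, -0.65, -4, 4.5)
    B <- matrix(c(0.18^2, 0.45 * 0.18 * 0.28,
                  0.45 * 0.18 * 0.28, 0.28^2), 2L, 2L)
    sigma <- 0.12
    bmat <- rbind(c(-0.05, 0.03),   # first.level
                  c(-0.08, 0.04),   # last.level
                  c(-0.40, 0.25),   # midpoint
                  c(0.30, -0.20))   # hill.slope
  } else {
    alpha <- c(-0.8, -0.25, -0.03, -3.5)
    B <- diag(c(0.35^2, 0.08^2, 0.02^2, 1.0^2))
    B[2L, 3L] <- B[3L, 2L] <- 0.3 * 0.08 * 0.02
    sigma <- 0.15
    bmat <- rbind(c(-0.10, 0.05),   # last.level
                  c(-0.03, 0.015),  # slope2
                  c(-0.006, 0.003), # slope1
                  c(-0.50, 0.30))   # changepoint
  }
  beta <- lapply(1:4, function(k) {
    if (n_covariates == 0L) numeric() else bmat[k, seq_len(n_covariates)]
  })
  pop_params(family, alpha, beta, B, sigma)
}

#' Simulation design
#'
#' Configuration of the longitudinal data-generating process used in the
#' performance study: a death-anchored follow-up window, annual visits with
#' uniform jitter of +/- 2 months on the inter-visit gaps, per-subject
#' follow-up durations calibrated to a target mean and SD, and an inclusion
#' filter requiring a minimum number of observations per subject.
#'
#' @param n_subjects number of retained subjects (subjects failing the
#'   inclusion filter are redrawn so the count is exact).
#' @param family model family used to generate trajectories.
#' @param truth generating [pop_params()]; defaults to
#'   [default_truth()] for the family and covariate count.
#' @param n_covariates covariates per parameter (0, 1 or 2), drawn standard
#'   normal at the subject level and shared across parameters.
#' @param window time window `c(earliest, 0)` (years; default -24 to 0).
#' @param followup_mean,followup_sd targets for the mean and SD of
#'   per-subject follow-up span (years; defaults 10 and 5).
#' @param followup_min shortest generable follow-up (years); together with
#'   the annual schedule it guarantees the inclusion filter is satisfiable.
#' @param visit_jitter half-width of the uniform jitter on inter-visit gaps
#'   (years; default 2 months).
#' @param min_observations inclusion threshold (default 4 visits).
#' @param v transition length when generating from the smooth piecewise
#'   family.
#' @return an object of class `sim_design`.
#' @export
simulation_design <- function(n_subjects = 100L,
                              family = c("smm", "pmm_abrupt", "pmm_smooth"),
                              truth = NULL,
                              n_covariates = 0L,
                              window = c(-24, 0),
                              followup_mean = 10,
                              followup_sd = 5,
                              followup_min = 3.4,
                              visit_jitter = 2 / 12,
                              min_observations = 4L,
                              v = 2) {
  family <- match.arg(family)
  if (is.null(truth)) truth <- default_truth(family, n_covariates)
  stopifnot(inherits(truth, "pop_params"), truth$family == family,
            n_subjects >= 1L, length(window) == 2L, window[1L] < window[2L],
            window[2L] <= 0, followup_mean > 0, followup_sd > 0,
            followup_min > 0, visit_jitter >= 0, min_observations >= 1L)
  if (followup_min + min_observations - 2 > -window[1L]) {
    stop("simulation_design: the minimum observation count is unreachable ",
         "inside the time window")
  }
  structure(list(n_subjects = as.integer(n_subjects), family = family,
                 truth = truth, n_covariates = as.integer(n_covariates),
                 window = window, followup_mean = followup_mean,
                 followup_sd = followup_sd, followup_min = followup_min,
                 visit_jitter = visit_jitter,
                 min_observations = as.integer(min_observations), v = v),
            class = "sim_design")
}

# Beta(a, b) shape parameters matching a mean and sd on [lo, hi]
beta_shapes <- function(mean, sd, lo, hi) {
  m <- (mean - lo) / (hi - lo)
  vr <- (sd / (hi - lo))^2
  if (m <= 0 || m >= 1) stop("follow-up mean outside its support")
  vmax <- m * (1 - m)
  if (vr >= vmax) vr <- 0.98 * vmax   # clamp: sd not representable exactly
  s <- vmax / vr - 1
  c(a = m * s, b = (1 - m) * s)
}

# visit schedule for one subject: annual gaps with uniform jitter, built
# backwards from a last visit in (-1, 0]
visit_times <- function(followup, window, jitter) {
  m <- round(followup) + 1L
  last <- -stats::runif(1L, 0, 0.9)
  if (m < 2L) return(last)
  gaps <- 1 + stats::runif(m - 1L, -jitter, jitter)
  tt <- last - rev(cumsum(rev(gaps)))
  tt <- c(tt, last)
  tt[tt >= window[1L]]
}

#' Generate a longitudinal dataset from a simulation design
#'
#' For each subject: a follow-up duration is drawn from a Beta distribution
#' scaled to the design's support and calibrated to the target follow-up
#' mean/SD; annual visits with uniform jitter on the gaps are laid out
#' backwards from a last visit within a year of time 0; covariates (if any)
#' are drawn standard normal; random effects are drawn from `MVN(0, B)`;
#' and outcomes are the structural mean plus `N(0, sigma^2)` noise.
#' Subjects with fewer than `min_observations` visits are discarded and
#' redrawn until exactly `n_subjects` remain.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed (all randomness is derived from it).
#' @return a list with `data` (a [long_data()] object with covariate
#'   columns `X1`, `X2` when requested), `psi` (the generating
#'   person-specific parameter matrix, one row per subject), `eta` (the
#'   generating random effects) and `design`.
#' @export
generate_simulation_dataset <- function(design, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  gen_longitudinal(design, covariate_sampler = function(n) {
    if (design$n_covariates == 0L) return(NULL)
    matrix(stats::rnorm(n * design$n_covariates), n, design$n_covariates,
           dimnames = list(NULL, paste0("X", seq_len(design$n_covariates))))
  })
}

# shared generator core; covariate_sampler(n) returns NULL or an n x p
# matrix with column names
gen_longitudinal <- function(design, covariate_sampler,
                             outcome_col = "outcome", id_offset = 0L) {
  tr <- design$truth
  d <- length(re_indices(tr$family))
  sh <- beta_shapes(design$followup_mean, design$followup_sd,
                    design$followup_min, -design$window[1L] - 1)
  need <- design$n_subjects
  rows <- list(); psis <- list(); etas <- list(); covs <- list()
  kept <- 0L
  while (kept < need) {
    batch <- max(8L, ceiling((need - kept) * 1.2))
    fu <- design$followup_min +
      (-design$window[1L] - 1 - design$followup_min) *
      stats::rbeta(batch, sh["a"], sh["b"])
    X <- covariate_sampler(batch)
    eta <- MASS::mvrnorm(batch, mu = rep(0, d), Sigma = tr$B)
    if (!is.matrix(eta)) eta <- matrix(eta, nrow = batch)
    for (s in seq_len(batch)) {
      tt <- visit_times(fu[s], design$window, design$visit_jitter)
      if (length(tt) < design$min_observations) next
      xrow <- if (is.null(X)) NULL else
        stats::setNames(as.numeric(X[s, ]), colnames(X))
      psi <- individual_parameters(tr, X = rep(list(xrow), 4L),
                                   eta = eta[s, ])
      mu <- structural_mean(tr$family, tt,
                            matrix(psi, length(tt), 4L, byrow = TRUE),
                            design$v)
      y <- mu + stats::rnorm(length(tt), 0, tr$sigma)
      kept <- kept + 1L
      rows[[kept]] <- data.frame(id = kept + id_offset, time = tt, y = y)
      psis[[kept]] <- psi
      etas[[kept]] <- eta[s, ]
      covs[kept] <- list(xrow)   # keeps NULL entries when no covariates
      if (kept >= need) break
    }
  }
  df <- do.call(rbind, rows)
  cov_names <- character()
  if (length(covs) && !is.null(covs[[1L]])) {
    cov_names <- names(covs[[1L]]) %||%
      paste0("X", seq_along(covs[[1L]]))
    cv <- do.call(rbind, covs)
    colnames(cv) <- cov_names
    for (nm in cov_names) df[[nm]] <- cv[match(df$id, seq_len(need) + id_offset), nm]
  }
  names(df)[names(df) == "y"] <- outcome_col
  data <- long_data(df, id = "id", outcome = outcome_col, time = "time",
                    covariates = cov_names)
  list(data = data,
       psi = do.call(rbind, psis),
       eta = do.call(rbind, etas),
       covariates = if (length(cov_names)) do.call(rbind, covs) else NULL,
       design = design)
}

# dispatch on family for generation and prediction
structural_mean <- function(family, t, psi, v = 0) {
  switch(family,
         smm = smm_mean(t, psi),
         pmm_abrupt = pmm_abrupt_mean(t, psi),
         pmm_smooth = pmm_smooth_mean(t, psi, v))
}

#' Generate the illustrative cognition-until-death dataset
#'
#' Emulates the packaged example data: 1200 individuals with annual
#' composite global-cognition testing until death (retrospective time in
#' years, 0 at death), a mean follow-up of about 7 years (SD about 5), at
#' least 4 visits each, and an age-at-death covariate (around 90 years)
#' that lowers the first and last cognitive levels and advances the
#' midpoint of decline. This is an emulation of the published descriptors,
#' not a replication of an undisclosed generating process.
#'
#' @param n_subjects number of individuals (default 1200).
#' @param seed integer seed.
#' @return a [long_data()] object with columns `ID`, `time`, `cognition`,
#'   `ageDeath`; the generating parameters are attached as attribute
#'   `"truth"`.
#' @export
generate_datacog <- function(n_subjects = 1200L, seed = 42L) {
  set.seed(seed)
  truth <- pop_params(
    "smm",
    alpha = c(0.45, -0.65, -4, 4.5),
    beta = list(-0.012, -0.025, -0.060, numeric()),
    B = matrix(c(0.18^2, 0.45 * 0.18 * 0.28,
                 0.45 * 0.18 * 0.28, 0.28^2), 2L, 2L),
    sigma = 0.12
  )
  design <- simulation_design(
    n_subjects = n_subjects, family = "smm", truth = truth,
    window = c(-20, 0), followup_mean = 7, followup_sd = 5,
    followup_min = 4.2, min_observations = 4L
  )
  age_sampler <- function(n) {
    age <- round(stats::rnorm(n, 90, 6.2))
    age <- pmin(pmax(age, 66), 108)
    matrix(age - 90, n, 1L, dimnames = list(NULL, "ageDeath90"))
  }
  sim <- gen_longitudinal(design, age_sampler, outcome_col = "cognition",
                          id_offset = 999L)
  df <- as.data.frame(sim$data)
  df$ageDeath <- df$ageDeath90 + 90
  df$ageDeath90 <- NULL
  names(df)[1:3] <- c("ID", "time", "cognition")
  out <- long_data(df, id = "ID", outcome = "cognition", time = "time",
                   covariates = "ageDeath")
  attr(out, "truth") <- truth
  attr(out, "psi") <- sim$psi
  out
}
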