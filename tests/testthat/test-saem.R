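# SAEM engine: determinism, covariance structure, degenerate recovery,
# standard errors, likelihoods and subject-level predictions

tiny_control <- function(seed) {
  saem_control(K1 = 40L, K2 = 30L, seed = seed, compute_is_loglik = FALSE,
               conv_window = 10L)
}

tiny_pmm_data <- function(seed = 51L, n = 40L) {
  d <- simulation_design(n_subjects = n, family = "pmm_abrupt")
  generate_simulation_dataset(d, seed = seed)$data
}

test_that("identical inputs and seed give bitwise-identical fits", {
  data <- tiny_pmm_data()
  spec <- model_spec("pmm_abrupt")
  f1 <- suppressWarnings(saem_fit(spec, data, control = tiny_control(5L)))
  f2 <- suppressWarnings(saem_fit(spec, data, control = tiny_control(5L)))
  f3 <- suppressWarnings(saem_fit(spec, data, control = tiny_control(6L)))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$eta_hat, f2$eta_hat)
  expect_false(identical(f1$trace, f3$trace))
})

test_that("smooth specification with v = 0 equals the abrupt fit", {
  data <- tiny_pmm_data(seed = 52L)
  fa <- suppressWarnings(saem_fit(model_spec("pmm_abrupt"), data,
                                  control = tiny_control(7L)))
  fs <- suppressWarnings(saem_fit(model_spec("pmm_smooth", v = 0), data,
                                  control = tiny_control(7L)))
  expect_identical(fa$trace, fs$trace)
})

test_that("estimated covariance keeps the family's structure", {
  fit <- small_pmm_fit()
  B <- fit$B
  expect_true(all(diag(B) > 0))
  off <- B; diag(off) <- 0
  free <- off != 0
  expect_true(all(which(free) %in% c(7L, 10L)))  # the (2,3)/(3,2) entries
  expect_gt(fit$sigma, 0)
  expect_equal(nrow(fit$trace), fit$control$K1 + fit$control$K2)
  sfit <- small_smm_fit()
  expect_equal(dim(sfit$B), c(2L, 2L))
  expect_gt(sfit$sigma, 0)
})

test_that("noiseless degenerate data are recovered almost exactly", {
  tr <- pop_params("pmm_abrupt", alpha = c(-0.8, -0.25, -0.03, -3.5),
                   B = diag(1e-12, 4), sigma = 1e-6)
  d <- simulation_design(n_subjects = 50L, family = "pmm_abrupt",
                         truth = tr)
  sim <- generate_simulation_dataset(d, seed = 9L)
  fit <- suppressWarnings(saem_fit(model_spec("pmm_abrupt"), sim$data,
                                   control = quick_control(9L)))
  al <- vapply(1:4, function(k) fit$theta[fit$prep$idx[[k]][1L]],
               numeric(1))
  expect_lt(max(abs(al - tr$alpha)), 1e-2)
  # with no between-subject variability the conditional random effects
  # collapse to zero
  expect_lt(max(abs(fit$eta_hat)), 0.05)
})

test_that("estimates table is internally consistent", {
  fit <- small_smm_fit()
  tab <- fit$estimates
  fx <- tab[!is.na(tab$p), ]
  expect_true(all(fx$p >= 0 & fx$p <= 1))
  expect_equal(fx$p, 2 * stats::pnorm(-abs(fx$z)))
  expect_equal(fx$z, fx$estimate / fx$se)
  expect_true(all(tab$se[!is.na(tab$se)] > 0))
  # covariate terms present for all four structural parameters
  expect_setequal(
    grep("^beta_", tab$term, value = TRUE),
    c("beta_ageDeath90(first.level)", "beta_ageDeath90(last.level)",
      "beta_ageDeath90(midpoint)", "beta_ageDeath90(hill.slope)"))
})

test_that("null covariates are rejected at close to the nominal rate", {
  # pure-noise covariate on the last level; at the 5% level, 10
  # replicates should almost never produce 4+ rejections
  rej <- 0L
  for (r in 1:10) {
    d <- simulation_design(n_subjects = 100L, family = "pmm_abrupt")
    sim <- generate_simulation_dataset(d, seed = 600L + r)
    df <- as.data.frame(sim$data)
    set.seed(700L + r)
    noise <- stats::rnorm(length(unique(df$id)))
    df$Z <- noise[match(df$id, unique(df$id))]
    ld <- long_data(df, id = "id", outcome = "y", time = "time",
                    covariates = "Z")
    spec <- model_spec("pmm_abrupt", covariates = list(last.level = "Z"))
    fit <- suppressWarnings(saem_fit(spec, ld,
                                     control = quick_control(600L + r)))
    pz <- fit$estimates$p[fit$estimates$term == "beta_Z(last.level)"]
    rej <- rej + (pz < 0.05)
  }
  expect_lte(rej, 3L)
})

test_that("both likelihood estimators reduce to the closed form without
           random effects", {
  fit <- small_pmm_fit()
  fit0 <- fit
  fit0$B <- diag(1e-14, 4L)
  fit0$eta_hat[] <- 0
  pp <- fit0$prep
  mu <- trajmix:::mu_matrix(pp, fit0$theta)
  f0 <- pmm_abrupt_mean(pp$t, mu[pp$subj, ])
  closed <- sum(stats::dnorm(pp$y, f0, fit0$sigma, log = TRUE))
  ll_lin <- log_likelihood(fit0, "linearization")
  ll_is <- log_likelihood(fit0, "importance_sampling", n_samples = 300L)
  expect_equal(ll_lin, closed, tolerance = 1e-3)
  expect_equal(ll_is, closed, tolerance = 1e-3)
})

test_that("linearized likelihood is exact for a linear submodel", {
  # with the changepoint variance removed the piecewise model is linear
  # in its remaining random effects, so the linearization must equal the
  # exact Gaussian marginal likelihood computed by direct algebra
  fit <- small_pmm_fit()
  fit0 <- fit
  fit0$B[4L, ] <- 0; fit0$B[, 4L] <- 0; fit0$B[4L, 4L] <- 1e-16
  fit0$eta_hat[, 4L] <- 0
  pp <- fit0$prep
  alpha <- vapply(1:4, function(k) fit0$theta[pp$idx[[k]][1L]], numeric(1))
  cp <- alpha[4L]
  B3 <- fit0$B[1:3, 1:3]
  s2 <- fit0$sigma^2
  ll <- 0
  for (i in seq_len(pp$N)) {
    rows <- which(pp$subj == i)
    tt <- pp$t[rows]
    M <- cbind(1, ifelse(tt < cp, cp, tt), ifelse(tt < cp, tt - cp, 0))
    V <- M %*% B3 %*% t(M) + diag(s2, length(rows))
    mcurve <- drop(M %*% alpha[1:3])
    L <- chol(V)
    u <- backsolve(L, pp$y[rows] - mcurve, transpose = TRUE)
    ll <- ll - 0.5 * (length(rows) * log(2 * pi) + sum(u^2)) -
      sum(log(diag(L)))
  }
  expect_equal(log_likelihood(fit0, "linearization"), ll, tolerance = 1e-6)
})

test_that("importance sampling tracks the linearization on a fitted model", {
  fit <- small_pmm_fit()
  ll_lin <- log_likelihood(fit, "linearization")
  # the linearization is itself an approximation for this nonlinear
  # model, so agreement is expected only to a few percent
  ll_is <- log_likelihood(fit, "importance_sampling", n_samples = 2000L)
  expect_lt(abs(ll_is - ll_lin) / abs(ll_lin), 0.05)
})

test_that("the true sigmoidal model beats a misspecified linear mixed
           model on sigmoid data", {
  fit <- small_smm_fit()
  ll_is <- log_likelihood(fit, "importance_sampling", n_samples = 1000L)
  df <- as.data.frame(fit$data)
  lmm <- lme4::lmer(y ~ time + (1 + time | id), data = df, REML = FALSE)
  expect_gt(ll_is, as.numeric(stats::logLik(lmm)))
})

test_that("smoothing phase stabilizes the parameter trace", {
  fit <- small_pmm_fit()
  K1 <- fit$control$K1; K2 <- fit$control$K2
  half <- floor(K2 / 2)
  first <- fit$trace[(K1 + 1):(K1 + half), , drop = FALSE]
  last <- fit$trace[(K1 + K2 - half + 1):(K1 + K2), , drop = FALSE]
  ratio <- apply(last, 2, stats::var) / pmax(apply(first, 2, stats::var),
                                             1e-300)
  expect_lt(stats::median(ratio), 1)
})

test_that("marginal trajectories follow the estimated fixed effects", {
  fit <- small_smm_fit()
  pop <- estimated_params(fit)
  grid <- seq(-15, 0, by = 1)
  mt <- marginal_trajectory(fit, times = grid,
                            profile = c(ageDeath90 = 0))
  # at time zero the sigmoid equals the last level for the profile
  expect_equal(mt$value[mt$time == 0], unname(pop$alpha[2]),
               tolerance = 1e-8)
  mt3 <- marginal_trajectory(fit, times = grid,
                             profile = c(ageDeath90 = 3))
  expect_equal(mt3$value[mt3$time == 0],
               unname(pop$alpha[2] + 3 * pop$beta[[2]][1]),
               tolerance = 1e-8)
  # group contrast at custom percentiles uses the covariate distribution
  mg <- marginal_trajectory(fit, times = grid, group = "ageDeath90",
                            group_probs = c(0.25, 0.75))
  expect_equal(length(unique(mg$group)), 2L)
  ages <- tapply(fit$data$ageDeath90, fit$data$id, `[`, 1)
  qs <- stats::quantile(ages, c(0.25, 0.75), names = FALSE)
  expect_true(all(grepl(sprintf("%.4g|%.4g", qs[1], qs[2]),
                        unique(mg$group))))
  expect_error(marginal_trajectory(fit, profile = c(other = 1)),
               "ageDeath90")
  # without covariates the curve ignores the profile entirely
  fitp <- small_pmm_fit()
  expect_equal(marginal_trajectory(fitp, times = grid)$value,
               marginal_trajectory(fitp, times = grid,
                                   profile = c(unused = 5))$value)
})

test_that("subject-level predictions centre the residuals", {
  fit <- small_pmm_fit()
  pr <- predict_individual(fit)
  expect_equal(nrow(pr$observations), fit$prep$n_obs)
  expect_lt(abs(mean(pr$observations$residual)), 0.02)
  one <- predict_individual(fit, subjects = fit$prep$ids[3])
  expect_equal(nrow(one$eta), 1L)
  expect_error(predict_individual(fit, subjects = "no-such-id"),
               "unknown subject")
})

test_that("small samples and sparse visit counts trigger warnings", {
  d <- simulation_design(n_subjects = 20L, family = "pmm_abrupt")
  sim <- generate_simulation_dataset(d, seed = 71L)
  w <- testthat::capture_warnings(
    saem_fit(model_spec("pmm_abrupt"), sim$data,
             control = tiny_control(71L)))
  expect_true(any(grepl("small sample", w)))
})
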