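#' Control settings for the SAEM algorithm
#'
#' Two-phase stochastic approximation EM: an exploration phase of `K1`
#' iterations with step size 1 (optionally with simulated annealing of the
#' variance components, which prevents their premature collapse), followed
#' by a smoothing phase of `K2` iterations with step size `1/(k - K1)`
#' during which the sufficient statistics are averaged.
#'
#' The E-step runs, per subject and per chain, one independence
#' Metropolis-Hastings proposal from the random-effect prior `N(0, B)`
#' followed by `mh_steps` sweeps of component-wise random-walk proposals
#' whose scales adapt during phase 1 towards an acceptance rate of about
#' 37%.
#'
#' @param K1,K2 iterations in the exploration and smoothing phases.
#' @param n_chains Markov chains per subject; `NULL` (default) picks
#'   `ceiling(200 / N)` capped at 10 (`ceiling(400 / N)` for the smooth
#'   piecewise family), so small samples get more chains.
#' @param mh_steps random-walk sweeps per E-step; `NULL` (default)
#'   resolves to 2, or 4 for the smooth piecewise family, whose
#'   transition window makes the conditional distribution of the
#'   changepoint harder to traverse.
#' @param annealing logical: inflate-then-release variance components
#'   during phase 1 (multiplicative floor decaying by 0.95 per iteration).
#' @param seed integer seed; every random draw in the fit derives from it.
#' @param likelihood_samples Monte-Carlo draws for the importance-sampling
#'   log-likelihood.
#' @param compute_is_loglik logical: compute the importance-sampling
#'   log-likelihood at the end of the fit (the linearized one is always
#'   computed).
#' @param adapt_target target acceptance rate of the random-walk kernel.
#' @param marginal_maxit BFGS iterations per M-step for structural
#'   parameters without random effects (sigmoidal midpoint and Hill slope).
#' @param conv_window,conv_tol convergence flag: every traced parameter
#'   must move by less than `conv_tol` (relative to its final magnitude,
#'   floored at 0.01; covariate coefficients are judged relative to the
#'   magnitude of the structural parameter they modify) between
#'   consecutive iterations throughout the last `conv_window` smoothing
#'   iterations.
#' @return a list of class `saem_control`.
#' @export
saem_control <- function(K1 = 300L, K2 = 300L, n_chains = NULL,
                         mh_steps = NULL, annealing = TRUE, seed = 1L,
                         likelihood_samples = 5000L,
                         compute_is_loglik = TRUE,
                         adapt_target = 0.375, marginal_maxit = 2L,
                         conv_window = 20L, conv_tol = 1e-3) {
  stopifnot(K1 >= 1L, K2 >= 1L, is.null(mh_steps) || mh_steps >= 1L,
            is.null(n_chains) || n_chains >= 1L,
            likelihood_samples >= 10L, conv_window >= 2L, conv_tol > 0)
  structure(list(K1 = as.integer(K1), K2 = as.integer(K2),
                 n_chains = n_chains,
                 mh_steps = if (is.null(mh_steps)) NULL else
                   as.integer(mh_steps),
                 annealing = isTRUE(annealing), seed = as.integer(seed),
                 likelihood_samples = as.integer(likelihood_samples),
                 compute_is_loglik = isTRUE(compute_is_loglik),
                 adapt_target = adapt_target,
                 marginal_maxit = as.integer(marginal_maxit),
                 conv_window = as.integer(conv_window),
                 conv_tol = conv_tol),
            class = "saem_control")
}

# internal: preprocess data + spec into flat estimation structures
prep_data <- function(spec, data) {
  stopifnot(inherits(spec, "trajmix_spec"), inherits(data, "long_data"))
  ids <- unique(data$id)
  N <- length(ids)
  subj <- match(data$id, ids)
  y <- data$y
  t <- data$time
  if (spec$family == "smm" && any(t > 0) && any(t < 0)) {
    stop("the sigmoidal model requires a consistent time sign convention ",
         "(all times <= 0 or all >= 0); refusing to fit")
  }
  warnings <- character()
  if (N < 30L) {
    warnings <- c(warnings, sprintf(
      "small sample: only %d subjects; estimates and standard errors may be unstable", N))
  }
  n_i <- tabulate(subj, N)
  if (any(n_i < 4L)) {
    warnings <- c(warnings, sprintf(
      "%d subject(s) have fewer than 4 observations", sum(n_i < 4L)))
  }
  first_row <- match(ids, data$id)   # data sorted by id, time
  D <- vector("list", 4L)
  idx <- vector("list", 4L)
  tf_names <- character()
  pos <- 0L
  for (k in 1:4) {
    cvs <- spec$covariates[[k]]
    if (length(cvs) > 3L) {
      warnings <- c(warnings, sprintf(
        "parameter %s carries %d covariates; consider a sparser model",
        spec$labels[k], length(cvs)))
    }
    Xk <- matrix(1, N, 1L)
    for (cv in cvs) {
      if (!cv %in% names(data)) {
        stop("covariate '", cv, "' not found in the data")
      }
      vals <- data[[cv]][first_row]
      if (!is.numeric(vals) || any(!is.finite(vals))) {
        stop("covariate '", cv, "' must be numeric and complete")
      }
      Xk <- cbind(Xk, vals)
    }
    D[[k]] <- Xk
    nm <- c(sprintf("alpha_(%s)", spec$labels[k]),
            if (length(cvs)) sprintf("beta_%s(%s)", cvs, spec$labels[k]))
    idx[[k]] <- pos + seq_along(nm)
    pos <- pos + length(nm)
    tf_names <- c(tf_names, nm)
  }
  tsign <- if (any(t < 0)) -1 else 1
  list(ids = ids, N = N, subj = subj, y = y, t = t, n_i = n_i,
       n_obs = length(y), D = D, idx = idx, tf_names = tf_names,
       family = spec$family, v = spec$v, labels = spec$labels,
       re_idx = re_indices(spec$family), mask = b_structure(spec$family),
       tsign = tsign, tscale = max(abs(t), 1e-8), warnings = warnings)
}

# engine-internal structural evaluation with domain clamps, so optimizer
# and sampler excursions never raise hard errors
f_eval_engine <- function(pp, t, psi) {
  if (pp$family == "smm") {
    eps3 <- 1e-3 * pp$tscale
    psi[, 3L] <- pp$tsign * pmax(pp$tsign * psi[, 3L], eps3)
    psi[, 4L] <- pmax(psi[, 4L], 0.02)
    smm_mean(t, psi)
  } else {
    structural_mean(pp$family, t, psi, pp$v)
  }
}

mu_matrix <- function(pp, tf) {
  out <- matrix(0, pp$N, 4L)
  for (k in 1:4) out[, k] <- drop(pp$D[[k]] %*% tf[pp$idx[[k]]])
  out
}

repair_B <- function(B, mask, family) {
  B[!mask] <- 0
  diag(B) <- pmax(diag(B), 1e-10)
  if (family == "smm") {
    ev <- eigen(B, symmetric = TRUE)
    if (min(ev$values) < 1e-12) {
      vals <- pmax(ev$values, 1e-10)
      B <- ev$vectors %*% (vals * t(ev$vectors))
      B <- (B + t(B)) / 2
    }
  } else {
    lim <- 0.99 * sqrt(B[2L, 2L] * B[3L, 3L])
    if (abs(B[2L, 3L]) > lim) {
      B[2L, 3L] <- B[3L, 2L] <- sign(B[2L, 3L]) * lim
    }
  }
  B
}

b_free_names <- function(pp) {
  lab <- pp$labels[pp$re_idx]
  d <- length(pp$re_idx)
  nm <- sprintf("var_(%s)", lab)
  for (j in seq_len(d)) for (k in seq_len(d)) {
    if (k > j && pp$mask[j, k]) {
      nm <- c(nm, sprintf("cov_(%s,%s)", lab[j], lab[k]))
    }
  }
  nm
}

b_free_values <- function(B, pp) {
  d <- length(pp$re_idx)
  out <- diag(B)
  for (j in seq_len(d)) for (k in seq_len(d)) {
    if (k > j && pp$mask[j, k]) out <- c(out, B[j, k])
  }
  out
}

#' Fit a structural model by SAEM
#'
#' Maximum-likelihood estimation of the sigmoidal or piecewise mixed model
#' by the two-phase stochastic approximation EM algorithm: a
#' Metropolis-Hastings E-step draws the subject-level random effects from
#' their conditional distribution; a stochastic-approximation step averages
#' the complete-data sufficient statistics; and a closed-form M-step
#' updates the fixed effects (generalised least squares on the sampled
#' person-specific parameters), the structured random-effect covariance
#' (empirical second moments restricted to the family's free entries) and
#' the residual variance. Structural parameters without random effects (the
#' sigmoidal midpoint and Hill slope) are updated by a nested quasi-Newton
#' maximization of the complete-data likelihood inside the M-step, with the
#' Hill slope kept positive through a log parameterization.
#'
#' Non-stabilization of the smoothing phase sets `converged_phase2 = FALSE`
#' with a warning rather than an error. Given identical inputs and seed the
#' fit is fully deterministic.
#'
#' @param spec a [model_spec()].
#' @param data a [long_data()] object.
#' @param start `NULL` (automatic initials), a numeric vector of length 4
#'   overriding the four main starting values element-wise (`NA` keeps the
#'   automatic value), or a `start_values` object.
#' @param control a [saem_control()].
#' @return an object of class `trajmix_fit`; see [fitted_table()],
#'   [marginal_trajectory()], [predict_individual()], [log_likelihood()],
#'   [convergence_plot()].
#' @export
saem_fit <- function(spec, data, start = NULL, control = saem_control()) {
  t0 <- proc.time()[["elapsed"]]
  pp <- prep_data(spec, data)
  set.seed(control$seed)
  warns <- pp$warnings

  # ---- starting values -------------------------------------------------
  auto <- if (pp$family == "smm") smm_initials(data) else pmm_initials(data)
  sv <- if (inherits(start, "start_values")) start else resolve_start(start, auto)
  vals <- sv$values
  if (pp$family == "smm") {
    if (!is.finite(vals[4L]) || vals[4L] <= 0) {
      warns <- c(warns, "non-positive Hill-slope start clamped to 0.1")
      vals[4L] <- 0.1
    }
    if (!is.finite(vals[3L]) || pp$tsign * vals[3L] <= 0) {
      warns <- c(warns, "midpoint start on the wrong side of zero; clamped")
      vals[3L] <- pp$tsign * max(abs(vals[3L]), 0.1 * pp$tscale)
    }
  }
  sv$values <- vals
  vstart <- start_variances(data, sv, pp$family, pp$v)

  # ---- state -----------------------------------------------------------
  K1 <- control$K1; K2 <- control$K2; K <- K1 + K2
  d <- length(pp$re_idx)
  N <- pp$N
  # the piecewise families carry a 4-dimensional random effect including
  # a changepoint whose conditional distribution mixes slowly; they get a
  # stronger E-step by default than the sigmoidal family, whose structural
  # model is linear in its two random effects
  pmm <- pp$family != "smm"
  chain_base <- if (pmm) 400 else 200
  C <- control$n_chains %||% min(10L, max(1L, ceiling(chain_base / N)))
  mh_steps <- control$mh_steps %||% (if (pmm) 4L else 2L)
  NC <- N * C
  tf <- numeric(length(pp$tf_names)); names(tf) <- pp$tf_names
  for (k in 1:4) tf[pp$idx[[k]][1L]] <- vals[k]
  B <- repair_B(vstart$B, pp$mask, pp$family)
  sigma2 <- vstart$sigma2

  rep_idx <- rep(seq_len(N), C)
  obs_rep <- rep(seq_len(pp$n_obs), C)
  t_rep <- pp$t[obs_rep]
  y_rep <- pp$y[obs_rep]
  subj_rep <- pp$subj[obs_rep] + rep((seq_len(C) - 1L) * N, each = pp$n_obs)

  E <- matrix(0, NC, d)
  rw_scale <- pmax(sqrt(diag(B)), 1e-3)
  # cross-products for the GLS fixed-effect update
  Dr <- pp$D[pp$re_idx]
  pk <- vapply(Dr, ncol, integer(1L))
  off <- c(0L, cumsum(pk))
  P <- lapply(seq_len(d), function(k)
    lapply(seq_len(d), function(l) crossprod(Dr[[k]], Dr[[l]])))

  S_phi <- NULL; S_phi2 <- NULL; S_rss <- NULL
  eta_sum <- matrix(0, N, d); eta_n <- 0L
  trace_names <- c(pp$tf_names, b_free_names(pp), "sigma")
  trace <- matrix(NA_real_, K, length(trace_names),
                  dimnames = list(NULL, trace_names))

  subj_all <- pp$subj[obs_rep]   # within-replicate subject of each obs row
  rss_of <- function(Emat, mu_obs) {
    psi <- mu_obs
    psi[, pp$re_idx] <- psi[, pp$re_idx] + Emat[subj_rep, , drop = FALSE]
    res <- y_rep - f_eval_engine(pp, t_rep, psi)
    drop(rowsum(res * res, subj_rep))
  }

  marg_par_names <- NULL
  if (pp$family == "smm") {
    # marginal block: (theta3, log(alpha4), beta4) optimized in the M-step
    i3 <- pp$idx[[3L]]; i4 <- pp$idx[[4L]]
    n3 <- length(i3); n4 <- length(i4)
    eps3 <- 1e-3 * pp$tscale
    obj_marg <- function(par, psi_base) {
      th3 <- par[seq_len(n3)]
      th4 <- par[n3 + seq_len(n4)]
      psi3 <- if (n3 == 1L) th3 else drop(pp$D[[3L]] %*% th3)
      psi4 <- if (n4 == 1L) exp(th4) else
        drop(pp$D[[4L]] %*% c(exp(th4[1L]), th4[-1L]))
      pen <- 0
      m3 <- pp$tsign * psi3
      bad3 <- m3 < eps3
      if (any(bad3)) {
        pen <- pen + 1e4 * sum((eps3 - m3[bad3])^2)
        psi3[bad3] <- pp$tsign * eps3
      }
      bad4 <- psi4 < 0.02
      if (any(bad4)) {
        pen <- pen + 1e4 * sum((0.02 - psi4[bad4])^2)
        psi4[bad4] <- 0.02
      }
      if (abs(th4[1L]) > log(200)) pen <- pen + 1e4 * (abs(th4[1L]) - log(200))^2
      psi_base[, 3L] <- if (n3 == 1L) psi3 else psi3[pp$subj]
      psi_base[, 4L] <- if (n4 == 1L) psi4 else psi4[pp$subj]
      r <- pp$y - smm_mean(pp$t, psi_base)
      sum(r * r) + pen
    }
    marg_par <- c(tf[i3], tf[i4])
    marg_par[length(i3) + 1L] <- log(tf[i4][1L])
  }

  chol_or_repair <- function(M) {
    tryCatch(chol(M), error = function(e) chol(M + diag(1e-8, nrow(M))))
  }

  # ---- iterations ------------------------------------------------------
  for (iter in seq_len(K)) {
    gamma <- if (iter <= K1) 1 else 1 / (iter - K1)
    phase1 <- iter <= K1
    mu <- mu_matrix(pp, tf)
    mu_obs <- mu[subj_all, , drop = FALSE]
    Bch <- chol_or_repair(B)
    W <- chol2inv(Bch)

    rss <- rss_of(E, mu_obs)
    q <- rowSums((E %*% W) * E)

    # kernel 1: independence proposal from the prior N(0, B)
    Ep <- matrix(stats::rnorm(NC * d), NC, d) %*% Bch
    prss <- rss_of(Ep, mu_obs)
    acc <- log(stats::runif(NC)) < (rss - prss) / (2 * sigma2)
    if (any(acc)) {
      E[acc, ] <- Ep[acc, , drop = FALSE]
      rss[acc] <- prss[acc]
      q <- rowSums((E %*% W) * E)
    }

    # kernel 2: component-wise random walk with adaptive scales
    for (s in seq_len(mh_steps)) {
      for (j in seq_len(d)) {
        Ep <- E
        Ep[, j] <- Ep[, j] + rw_scale[j] * stats::rnorm(NC)
        prss <- rss_of(Ep, mu_obs)
        qp <- rowSums((Ep %*% W) * Ep)
        acc <- log(stats::runif(NC)) <
          (rss - prss) / (2 * sigma2) + (q - qp) / 2
        if (any(acc)) {
          E[acc, j] <- Ep[acc, j]
          rss[acc] <- prss[acc]
          q[acc] <- qp[acc]
        }
        if (phase1) {
          rate <- mean(acc)
          rw_scale[j] <- rw_scale[j] *
            exp(min(0.1, 5 / iter) * (rate - control$adapt_target))
        }
      }
    }

    # ---- sufficient statistics ----------------------------------------
    phi_all <- mu[rep_idx, pp$re_idx, drop = FALSE] + E
    phi_bar <- rowsum(phi_all, rep_idx) / C
    phi2 <- crossprod(phi_all) / C
    rss_stat <- sum(rss) / C
    if (is.null(S_phi)) {
      S_phi <- phi_bar; S_phi2 <- phi2; S_rss <- rss_stat
    } else {
      S_phi <- S_phi + gamma * (phi_bar - S_phi)
      S_phi2 <- S_phi2 + gamma * (phi2 - S_phi2)
      S_rss <- S_rss + gamma * (rss_stat - S_rss)
    }
    if (!phase1) {
      eta_sum <- eta_sum + rowsum(E, rep_idx) / C
      eta_n <- eta_n + 1L
    }

    # ---- M-step ---------------------------------------------------------
    ptot <- sum(pk)
    A <- matrix(0, ptot, ptot)
    b <- numeric(ptot)
    for (k in seq_len(d)) {
      rk <- off[k] + seq_len(pk[k])
      for (l in seq_len(d)) {
        rl <- off[l] + seq_len(pk[l])
        A[rk, rl] <- W[k, l] * P[[k]][[l]]
        b[rk] <- b[rk] + W[k, l] * drop(crossprod(Dr[[k]], S_phi[, l]))
      }
    }
    theta_r <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(theta_r)) {
      stop("SAEM M-step failed at iteration ", iter,
           ": singular fixed-effect system (non-finite objective)")
    }
    for (k in seq_len(d)) {
      tf[pp$idx[[pp$re_idx[k]]]] <- theta_r[off[k] + seq_len(pk[k])]
    }
    mu_re <- matrix(0, N, d)
    for (k in seq_len(d)) {
      mu_re[, k] <- drop(Dr[[k]] %*% theta_r[off[k] + seq_len(pk[k])])
    }
    Bhat <- (S_phi2 - crossprod(mu_re, S_phi) - crossprod(S_phi, mu_re) +
               crossprod(mu_re)) / N
    Bhat <- (Bhat + t(Bhat)) / 2
    if (control$annealing && phase1) {
      diag(Bhat) <- pmax(diag(Bhat), 0.95 * diag(B))
    }
    B <- repair_B(Bhat, pp$mask, pp$family)
    s2hat <- S_rss / pp$n_obs
    sigma2 <- if (control$annealing && phase1) {
      max(s2hat, 0.95 * sigma2)
    } else s2hat
    if (!is.finite(sigma2) || sigma2 <= 0) {
      stop("SAEM M-step failed at iteration ", iter,
           ": non-finite residual variance")
    }

    if (pp$family == "smm") {
      psi_base <- cbind(S_phi[pp$subj, 1L], S_phi[pp$subj, 2L], 0, 0)
      # warm-started quasi-Newton: a few iterations per M-step suffice
      # once past the first exploration iterations
      opt <- stats::optim(marg_par, obj_marg, psi_base = psi_base,
                          method = "BFGS",
                          control = list(maxit = if (iter <= 20L) 10L else
                                           control$marginal_maxit,
                                         reltol = 1e-10))
      marg_par <- opt$par
      tf[i3] <- marg_par[seq_along(i3)]
      a4 <- exp(marg_par[length(i3) + 1L])
      tf[i4] <- c(a4, marg_par[-seq_len(length(i3) + 1L)])
    }

    trace[iter, ] <- c(tf, b_free_values(B, pp), sqrt(sigma2))
  }

  # ---- convergence flag ------------------------------------------------
  w <- min(control$conv_window, K2 - 1L)
  seg <- trace[(K - w):K, , drop = FALSE]
  steps <- abs(diff(seg))
  # scale floor: a covariate coefficient is judged relative to the
  # magnitude of the structural parameter it modifies, so that
  # near-zero effects do not make the relative criterion unattainable
  denom <- pmax(abs(trace[K, ]), 0.01)
  for (k in 1:4) {
    cols <- pp$idx[[k]]
    denom[cols] <- pmax(denom[cols], abs(trace[K, cols[1L]]))
  }
  # a covariance's natural scale is the geometric mean of its variances
  # (steps are then measured in correlation units)
  dfree <- length(pp$re_idx)
  vcols <- length(tf) + seq_len(dfree)
  ccol <- length(tf) + dfree
  for (j in seq_len(dfree)) for (l in seq_len(dfree)) {
    if (l > j && pp$mask[j, l]) {
      ccol <- ccol + 1L
      denom[ccol] <- max(denom[ccol],
                         sqrt(trace[K, vcols[j]] * trace[K, vcols[l]]))
    }
  }
  relstep <- max(sweep(steps, 2L, denom, "/"))
  converged <- is.finite(relstep) && relstep < control$conv_tol
  if (!converged) {
    warns <- c(warns, sprintf(
      "smoothing phase not stabilized: max relative parameter step %.2g over the last %d iterations (tolerance %g)",
      relstep, w, control$conv_tol))
  }

  eta_hat <- eta_sum / max(eta_n, 1L)
  mu <- mu_matrix(pp, tf)
  psi_hat <- mu
  psi_hat[, pp$re_idx] <- psi_hat[, pp$re_idx] + eta_hat
  fitted_y <- f_eval_engine(pp, pp$t, psi_hat[pp$subj, , drop = FALSE])
  dimnames(psi_hat) <- list(NULL, pp$labels)
  colnames(eta_hat) <- pp$labels[pp$re_idx]

  fit <- structure(list(
    spec = spec, control = control, data = data, prep = pp,
    start = sv, start_variances = vstart,
    theta = tf, B = B, sigma = sqrt(sigma2),
    trace = trace, converged_phase2 = converged,
    eta_hat = eta_hat, psi_hat = psi_hat, fitted = fitted_y,
    n_chains = C, rw_scale = rw_scale,
    warnings = warns, seed = control$seed
  ), class = "trajmix_fit")

  # ---- standard errors, p-values, likelihoods --------------------------
  se <- compute_standard_errors(fit)
  fit$estimates <- se$table
  fit$vcov_fixed <- se$vcov_fixed
  fit$se_variance <- se$se_variance
  fit$warnings <- c(fit$warnings, se$warnings)
  fit$loglik_linearization <- log_likelihood(fit, "linearization")
  fit$loglik_importance_sampling <-
    if (control$compute_is_loglik) {
      log_likelihood(fit, "importance_sampling",
                     n_samples = control$likelihood_samples)
    } else NA_real_
  np <- length(tf) + length(b_free_values(B, pp)) + 1L
  fit$n_parameters <- np
  fit$AIC <- -2 * fit$loglik_linearization + 2 * np
  fit$BIC <- -2 * fit$loglik_linearization + log(N) * np
  fit$runtime_seconds <- proc.time()[["elapsed"]] - t0
  for (wmsg in unique(fit$warnings)) warning(wmsg, call. = FALSE)
  fit
}

#' Population-parameter estimates of a fit
#'
#' @param fit a `trajmix_fit`.
#' @return the estimated [pop_params()] object.
#' @export
estimated_params <- function(fit) {
  stopifnot(inherits(fit, "trajmix_fit"))
  pp <- fit$prep
  alpha <- vapply(1:4, function(k) fit$theta[pp$idx[[k]][1L]], numeric(1L))
  beta <- lapply(1:4, function(k) unname(fit$theta[pp$idx[[k]][-1L]]))
  pop_params(pp$family, alpha, beta, fit$B, fit$sigma)
}

#' @export
coef.trajmix_fit <- function(object, ...) object$theta

#' @export
logLik.trajmix_fit <- function(object, ...) {
  structure(object$loglik_linearization, df = object$n_parameters,
            class = "logLik")
}
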