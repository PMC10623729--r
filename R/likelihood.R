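# linearization of the structural model around the conditional means of
# the random effects: first-order expansion f(eta) ~ f(eta_hat) +
# Z (eta - eta_hat), giving the Gaussian marginal y_i ~ N(f_i - Z_i
# eta_hat_i, Z_i B Z_i' + sigma^2 I) used for the Fisher information and
# the linearized log-likelihood

f_at_eta <- function(pp, tf, eta) {
  mu <- mu_matrix(pp, tf)
  psi <- mu
  psi[, pp$re_idx] <- psi[, pp$re_idx] + eta
  f_eval_engine(pp, pp$t, psi[pp$subj, , drop = FALSE])
}

# numeric Jacobians at the estimate: Z (n_obs x d, wrt eta) and A
# (n_obs x p, wrt the fixed effects), both vectorised across subjects
linearize_fit <- function(fit) {
  pp <- fit$prep
  tf <- fit$theta
  eta <- fit$eta_hat
  d <- ncol(eta)
  p <- length(tf)
  f0 <- f_at_eta(pp, tf, eta)
  Z <- matrix(0, pp$n_obs, d)
  for (j in seq_len(d)) {
    h <- 1e-4 * (1 + sqrt(fit$B[j, j]))
    ep <- eta; ep[, j] <- ep[, j] + h
    em <- eta; em[, j] <- em[, j] - h
    Z[, j] <- (f_at_eta(pp, tf, ep) - f_at_eta(pp, tf, em)) / (2 * h)
  }
  A <- matrix(0, pp$n_obs, p)
  for (m in seq_len(p)) {
    h <- 1e-5 * (1 + abs(tf[m]))
    tp <- tf; tp[m] <- tp[m] + h
    tm <- tf; tm[m] <- tm[m] - h
    A[, m] <- (f_at_eta(pp, tp, eta) - f_at_eta(pp, tm, eta)) / (2 * h)
  }
  list(f0 = f0, Z = Z, A = A)
}

#' Standard errors and Wald tests
#'
#' Fisher information from the linearization of the structural model
#' around the conditional means of the random effects. The fixed-effect
#' block is \eqn{\sum_i A_i' V_i^{-1} A_i} with marginal covariance
#' \eqn{V_i = Z_i B Z_i' + \sigma^2 I}; the variance-component block uses
#' the standard Gaussian trace formula
#' \eqn{\tfrac12 \mathrm{tr}(V^{-1}\dot V_a V^{-1}\dot V_b)}. Each fixed
#' effect gets a two-sided Wald p-value against the standard normal
#' reference (no small-sample degrees-of-freedom correction).
#'
#' @param fit a `trajmix_fit`.
#' @return a list with `table` (term, estimate, se, z, p for fixed effects;
#'   variance components carry an SE but no test), `vcov_fixed`,
#'   `se_variance` and `warnings`. A singular information matrix yields
#'   `NA` standard errors and a warning naming the parameters.
#' @export
compute_standard_errors <- function(fit) {
  pp <- fit$prep
  lin <- linearize_fit(fit)
  d <- ncol(fit$eta_hat)
  p <- length(fit$theta)
  sigma2 <- fit$sigma^2
  # variance parameters: free entries of B then sigma^2
  vnames <- c(b_free_names(pp), "sigma")
  pairs <- list()
  for (j in seq_len(d)) pairs[[length(pairs) + 1L]] <- c(j, j)
  for (j in seq_len(d)) for (k in seq_len(d)) {
    if (k > j && pp$mask[j, k]) pairs[[length(pairs) + 1L]] <- c(j, k)
  }
  nv <- length(pairs) + 1L
  Iff <- matrix(0, p, p)
  Ivv <- matrix(0, nv, nv)
  row_of <- split(seq_len(pp$n_obs), pp$subj)
  for (i in seq_len(pp$N)) {
    rows <- row_of[[i]]
    Zi <- lin$Z[rows, , drop = FALSE]
    Ai <- lin$A[rows, , drop = FALSE]
    Vi <- Zi %*% fit$B %*% t(Zi) + diag(sigma2, length(rows))
    ok <- TRUE
    Vinv <- tryCatch(chol2inv(chol(Vi)), error = function(e) {ok <<- FALSE; NULL})
    if (!ok) next
    Iff <- Iff + crossprod(Ai, Vinv %*% Ai)
    U <- vector("list", nv)
    for (a in seq_along(pairs)) {
      jk <- pairs[[a]]
      M <- tcrossprod(Zi[, jk[1L]], Zi[, jk[2L]])
      if (jk[1L] != jk[2L]) M <- M + t(M)
      U[[a]] <- Vinv %*% M
    }
    U[[nv]] <- Vinv
    for (a in seq_len(nv)) for (b in a:nv) {
      v <- 0.5 * sum(U[[a]] * t(U[[b]]))
      Ivv[a, b] <- Ivv[a, b] + v
      if (b > a) Ivv[b, a] <- Ivv[b, a] + v
    }
  }
  warns <- character()
  vcov_fixed <- tryCatch(solve(Iff), error = function(e) NULL)
  if (is.null(vcov_fixed) || any(!is.finite(diag(vcov_fixed))) ||
      any(diag(vcov_fixed) < 0)) {
    bad <- if (is.null(vcov_fixed)) names(fit$theta) else
      names(fit$theta)[!is.finite(diag(vcov_fixed)) | diag(vcov_fixed) < 0]
    warns <- c(warns, paste0(
      "singular Fisher information for fixed effects: standard errors ",
      "undefined for ", paste(bad, collapse = ", ")))
    if (is.null(vcov_fixed)) {
      vcov_fixed <- matrix(NA_real_, p, p)
    } else {
      diag(vcov_fixed)[diag(vcov_fixed) < 0] <- NA_real_
    }
  }
  dimnames(vcov_fixed) <- list(names(fit$theta), names(fit$theta))
  se_f <- sqrt(diag(vcov_fixed))
  # variance block: delta method for sigma (parameterized as sigma^2)
  se_v <- rep(NA_real_, nv)
  Ivv_inv <- tryCatch(solve(Ivv), error = function(e) NULL)
  if (!is.null(Ivv_inv) && all(is.finite(diag(Ivv_inv)))) {
    dv <- diag(Ivv_inv)
    dv[dv < 0] <- NA_real_
    se_v <- sqrt(dv)
    se_v[nv] <- se_v[nv] / (2 * fit$sigma)   # sigma^2 -> sigma
  } else {
    warns <- c(warns, "singular Fisher information for variance components")
  }
  names(se_v) <- vnames
  z <- fit$theta / se_f
  pval <- 2 * stats::pnorm(-abs(z))
  pval[fit$theta == 0] <- 1
  vvals <- c(b_free_values(fit$B, pp), fit$sigma)
  table <- rbind(
    data.frame(term = names(fit$theta), estimate = unname(fit$theta),
               se = unname(se_f), z = unname(z), p = unname(pval),
               stringsAsFactors = FALSE),
    data.frame(term = vnames, estimate = vvals, se = unname(se_v),
               z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  )
  rownames(table) <- NULL
  list(table = table, vcov_fixed = vcov_fixed, se_variance = se_v,
       warnings = warns)
}

#' Marginal log-likelihood of a fitted model
#'
#' Two estimators of the observed-data log-likelihood integrated over the
#' random effects: `"linearization"` uses the Gaussian marginal of the
#' first-order expansion of the structural model around the conditional
#' means (Lindstrom-Bates style); `"importance_sampling"` integrates by
#' Monte Carlo with a Gaussian proposal centred at each subject's
#' conditional mean with the linearized conditional covariance (falling
#' back to the prior `N(0, B)` for subjects whose proposal covariance is
#' degenerate, with a warning).
#'
#' @param fit a `trajmix_fit`.
#' @param method `"linearization"` or `"importance_sampling"`.
#' @param n_samples Monte-Carlo draws for importance sampling.
#' @return the total log-likelihood (a single number).
#' @export
log_likelihood <- function(fit, method = c("linearization",
                                           "importance_sampling"),
                           n_samples = fit$control$likelihood_samples) {
  method <- match.arg(method)
  pp <- fit$prep
  lin <- linearize_fit(fit)
  sigma2 <- fit$sigma^2
  row_of <- split(seq_len(pp$n_obs), pp$subj)
  if (method == "linearization") {
    ll <- 0
    for (i in seq_len(pp$N)) {
      rows <- row_of[[i]]
      Zi <- lin$Z[rows, , drop = FALSE]
      Vi <- Zi %*% fit$B %*% t(Zi) + diag(sigma2, length(rows))
      mi <- lin$f0[rows] - drop(Zi %*% fit$eta_hat[i, ])
      L <- chol(Vi)
      u <- backsolve(L, pp$y[rows] - mi, transpose = TRUE)
      ll <- ll - 0.5 * (length(rows) * log(2 * pi) + sum(u * u)) -
        sum(log(diag(L)))
    }
    return(ll)
  }
  # importance sampling
  set.seed(fit$seed + 100003L)
  d <- ncol(fit$eta_hat)
  N <- pp$N
  W <- chol2inv(chol_safe(fit$B))
  logdetB <- 2 * sum(log(diag(chol_safe(fit$B))))
  Larr <- array(0, c(N, d, d))     # chol factors (lower) of proposal cov
  Harr <- array(0, c(N, d, d))     # proposal precisions
  logdetG <- numeric(N)
  centre <- fit$eta_hat
  fellback <- FALSE
  for (i in seq_len(N)) {
    rows <- row_of[[i]]
    Zi <- lin$Z[rows, , drop = FALSE]
    H <- crossprod(Zi) / sigma2 + W
    ok <- TRUE
    G <- tryCatch(chol2inv(chol(H)), error = function(e) {ok <<- FALSE; NULL})
    if (!ok || any(!is.finite(G))) {
      fellback <- TRUE
      G <- fit$B + diag(1e-10, d)
      H <- W
      centre[i, ] <- 0
    }
    L <- t(chol_safe(G))
    Larr[i, , ] <- L
    Harr[i, , ] <- if (ok) H else W
    logdetG[i] <- 2 * sum(log(diag(L)))
  }
  if (fellback) {
    warning("importance sampling: degenerate proposal covariance for some ",
            "subjects; fell back to the prior proposal", call. = FALSE)
  }
  M <- as.integer(n_samples)
  logw <- matrix(0, N, M)
  for (m in seq_len(M)) {
    z <- matrix(stats::rnorm(N * d), N, d)
    eta <- centre
    for (a in seq_len(d)) for (b in seq_len(a)) {
      eta[, a] <- eta[, a] + Larr[, a, b] * z[, b]
    }
    res <- pp$y - f_at_eta(pp, fit$theta, eta)
    rss <- drop(rowsum(res * res, pp$subj))
    lly <- -0.5 * (pp$n_i * log(2 * pi * sigma2) + rss / sigma2)
    qB <- rowSums((eta %*% W) * eta)
    lprior <- -0.5 * (d * log(2 * pi) + logdetB + qB)
    u <- eta - centre
    qH <- numeric(N)
    for (a in seq_len(d)) for (b in seq_len(d)) {
      qH <- qH + u[, a] * Harr[, a, b] * u[, b]
    }
    lprop <- -0.5 * (d * log(2 * pi) + logdetG + qH)
    logw[, m] <- lly + lprior - lprop
  }
  mx <- apply(logw, 1L, max)
  sum(mx + log(rowMeans(exp(logw - mx))))
}

chol_safe <- function(M) {
  tryCatch(chol(M), error = function(e) chol(M + diag(1e-10, nrow(M))))
}
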