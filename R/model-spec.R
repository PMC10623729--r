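#' Model specification
#'
#' Describes which structural family is fitted, which covariates enter each
#' of the four structural parameters, and (for the smooth piecewise model)
#' the fixed transition length `v`.
#'
#' Covariates supplied through `var_all` are added to all four parameter
#' lists. Parameter-specific lists use the family's own vocabulary:
#' for the sigmoidal family `first.level`, `last.level`, `midpoint`,
#' `hill.slope` map to `psi1..psi4`; for the piecewise families
#' `last.level`, `slope2` (late segment, the one containing time 0),
#' `slope1` (early segment) and `changepoint` map to `psi1..psi4`.
#'
#' @param family one of `"smm"`, `"pmm_abrupt"`, `"pmm_smooth"`.
#' @param covariates named list of character vectors of covariate names,
#'   keyed by parameter label (see Details); missing entries mean no
#'   covariates on that parameter.
#' @param var_all character vector of covariates applied to all four
#'   parameters.
#' @param v fixed transition length for `pmm_smooth` (time units,
#'   default 2); `v = 0` reduces the smooth model to the abrupt one.
#' @return an object of class `trajmix_spec`.
#' @export
model_spec <- function(family = c("smm", "pmm_abrupt", "pmm_smooth"),
                       covariates = list(), var_all = character(), v = 2) {
  family <- match.arg(family)
  labels <- param_labels(family)
  stopifnot(is.list(covariates))
  bad <- setdiff(names(covariates), labels)
  if (length(bad)) {
    stop("model_spec: unknown parameter label(s) ", paste(bad, collapse = ", "),
         "; expected among ", paste(labels, collapse = ", "))
  }
  cov <- vector("list", 4L)
  names(cov) <- labels
  for (k in 1:4) {
    cov[[k]] <- unique(c(as.character(var_all),
                         as.character(covariates[[labels[k]]])))
  }
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
    stop("model_spec: v must be a single non-negative number")
  }
  if (family == "pmm_smooth" && v == 0) family <- "pmm_abrupt"
  if (family != "pmm_smooth") v <- 0
  structure(
    list(family = family, covariates = cov, v = v, labels = labels),
    class = "trajmix_spec"
  )
}

#' @export
print.trajmix_spec <- function(x, ...) {
  cat("Model specification:", family_name(x$family), "\n")
  if (x$family == "pmm_smooth") cat("  transition length v =", x$v, "\n")
  for (k in 1:4) {
    cv <- x$covariates[[k]]
    cat(sprintf("  %-12s ~ %s\n", x$labels[k],
                if (length(cv)) paste(cv, collapse = " + ") else "1"))
  }
  invisible(x)
}

family_name <- function(family) {
  switch(family,
         smm = "sigmoidal mixed model",
         pmm_abrupt = "piecewise mixed model (abrupt change)",
         pmm_smooth = "piecewise mixed model (smooth polynomial transition)")
}

#' Parameter labels of a model family
#' @param family model family string.
#' @return character vector of 4 labels in `psi1..psi4` order.
#' @export
param_labels <- function(family) {
  if (family == "smm") {
    c("first.level", "last.level", "midpoint", "hill.slope")
  } else {
    c("last.level", "slope2", "slope1", "changepoint")
  }
}

# indices (within psi1..psi4) of parameters carrying random effects
re_indices <- function(family) {
  if (family == "smm") 1:2 else 1:4
}

# logical mask of free entries of the random-effect covariance B
b_structure <- function(family) {
  if (family == "smm") {
    matrix(TRUE, 2L, 2L)
  } else {
    m <- diag(4L) > 0
    m[2L, 3L] <- m[3L, 2L] <- TRUE
    m
  }
}

#' Population parameters
#'
#' Container for the fixed effects (`alpha`, `beta`), the random-effect
#' covariance matrix `B` and the residual standard deviation `sigma` of a
#' structural model. For the sigmoidal family `B` is 2x2 (random effects on
#' the first and last level, free correlation); for the piecewise families
#' `B` is 4x4, diagonal except for a free covariance between the two slope
#' random effects. Entries of `B` outside the family's free structure are
#' forced to zero.
#'
#' @param family model family string.
#' @param alpha numeric vector of 4 parameter means (`psi1..psi4` order).
#' @param beta list of 4 numeric vectors of covariate coefficients (may be
#'   empty); recycled to empty when omitted.
#' @param B random-effect covariance matrix (2x2 or 4x4), or a vector of
#'   standard deviations from which a diagonal `B` is built.
#' @param sigma residual standard deviation (> 0).
#' @return object of class `pop_params`.
#' @export
pop_params <- function(family, alpha, beta = NULL, B = NULL, sigma = 1) {
  stopifnot(family %in% c("smm", "pmm_abrupt", "pmm_smooth"),
            is.numeric(alpha), length(alpha) == 4L, all(is.finite(alpha)),
            is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  d <- length(re_indices(family))
  if (is.null(beta)) beta <- rep(list(numeric()), 4L)
  stopifnot(is.list(beta), length(beta) == 4L)
  beta <- lapply(beta, as.numeric)
  if (is.null(B)) B <- diag(0, d)
  if (!is.matrix(B)) B <- diag(as.numeric(B)^2, d)
  stopifnot(nrow(B) == d, ncol(B) == d)
  if (max(abs(B - t(B))) > 1e-8 * (1 + max(abs(B)))) {
    stop("pop_params: B must be symmetric")
  }
  mask <- b_structure(family)
  B[!mask] <- 0
  if (min(eigen(B, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("pop_params: B must be positive semi-definite")
  }
  if (family == "smm" && alpha[4L] <= 0) {
    stop("pop_params: the Hill slope mean (alpha4) must be positive")
  }
  labels <- param_labels(family)
  names(alpha) <- labels
  names(beta) <- labels
  dimnames(B) <- list(labels[re_indices(family)], labels[re_indices(family)])
  structure(list(family = family, alpha = alpha, beta = beta, B = B,
                 sigma = sigma),
            class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population parameters (", family_name(x$family), ")\n", sep = "")
  cat("  alpha:", paste(sprintf("%s=%.4g", names(x$alpha), x$alpha),
                        collapse = ", "), "\n")
  for (k in 1:4) {
    if (length(x$beta[[k]])) {
      cat("  beta[", names(x$beta)[k], "]: ",
          paste(sprintf("%.4g", x$beta[[k]]), collapse = ", "), "\n", sep = "")
    }
  }
  cat("  sigma:", format(x$sigma, digits = 4), "\n")
  cat("  B:\n")
  print(round(x$B, 6))
  invisible(x)
}
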