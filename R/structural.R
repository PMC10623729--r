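#' Structural mean models
#'
#' Pure evaluation of the three structural mean trajectories used throughout
#' the package: the four-parameter sigmoidal model, the piecewise linear
#' model with an abrupt changepoint, and the piecewise linear model with a
#' smooth cubic transition of fixed length `v`.
#'
#' All three functions are vectorised over `t`. `psi` may be a numeric
#' vector of length 4 (one parameter set for every time point) or a numeric
#' matrix with `length(t)` rows and 4 columns (one parameter set per time
#' point, as used internally when each observation belongs to a different
#' subject).
#'
#' For the sigmoidal model the four parameters are
#' `psi1` (first level, the asymptote far from time 0), `psi2` (last level,
#' the value at time 0), `psi3` (midpoint, the time at which half of the
#' total change has occurred) and `psi4` (Hill slope, a positive
#' dimensionless exponent):
#' \deqn{f(t) = \psi_1 + (\psi_2 - \psi_1) / (1 + (t/\psi_3)^{\psi_4}).}
#' The ratio `t/psi3` must be non-negative: times and the midpoint must lie
#' on the same half-line (all non-positive for death-anchored time, or all
#' non-negative). `0^psi4` is defined as 0 for `psi4 > 0`, so `f(0) = psi2`
#' exactly.
#'
#' For the piecewise models the parameters are `psi1` (last level, the value
#' at time 0), `psi2` (slope of the late segment, the one containing time
#' 0), `psi3` (slope of the early segment) and `psi4` (changepoint time; for
#' the smooth model, the time at which the transition window of length `v`
#' begins). The abrupt model is
#' \deqn{f(t) = \psi_1 + \psi_2\psi_4 + \psi_3 (t - \psi_4)} for
#' `t < psi4` and \deqn{f(t) = \psi_1 + \psi_2 t} for `t >= psi4`; it is
#' continuous at the changepoint.
#'
#' The smooth model replaces the kink by a cubic polynomial on
#' `[psi4, psi4 + v]` whose value and first derivative match the early line
#' `lambda + psi3 t` at `psi4` and the late line `psi1 + psi2 t` at
#' `psi4 + v`, where the early-line intercept is constrained to
#' \deqn{\lambda = \psi_1 + (\psi_2 - \psi_3)(\psi_4 + v/2)} so that the two
#' lines intersect at the middle of the transition window. With `v = 0` the
#' smooth model coincides with the abrupt model at every `t`.
#'
#' @param t numeric vector of observation times (study timescale; may be
#'   negative, e.g. years before death).
#' @param psi numeric vector of length 4 or matrix (`length(t)` x 4) of
#'   structural parameters (see Details).
#' @param v non-negative scalar, length of the smooth transition window in
#'   time units.
#' @return numeric vector of mean outcome values, one per element of `t`.
#' @examples
#' smm_mean(c(-10, -5, 0), c(1, 0, -5, 2))
#' pmm_abrupt_mean(c(-10, -4, 0), c(0.3, -0.1, -0.02, -4))
#' pmm_smooth_mean(c(-10, -4, 0), c(0.3, -0.1, -0.02, -4), v = 1)
#' @export
smm_mean <- function(t, psi) {
  psi <- psi_rows(psi, length(t))
  p3 <- psi[, 3L]
  if (any(!is.finite(p3)) || any(p3 == 0)) {
    stop("smm_mean: midpoint parameter psi3 must be finite and non-zero")
  }
  r <- t / p3
  if (any(r < 0)) {
    stop("smm_mean: t/psi3 < 0; times and the midpoint must share the ",
         "same sign convention")
  }
  # r^psi4 via exp(psi4 * log r); log(0) = -Inf gives r^psi4 = 0 for psi4 > 0
  pow <- exp(psi[, 4L] * log(r))
  pow[r == 0] <- 0
  psi[, 1L] + (psi[, 2L] - psi[, 1L]) / (1 + pow)
}

#' @rdname smm_mean
#' @export
pmm_abrupt_mean <- function(t, psi) {
  psi <- psi_rows(psi, length(t))
  if (any(!is.finite(psi))) stop("pmm_abrupt_mean: non-finite parameter")
  early <- t < psi[, 4L]
  out <- psi[, 1L] + psi[, 2L] * t
  if (any(early)) {
    out[early] <- psi[early, 1L] + psi[early, 2L] * psi[early, 4L] +
      psi[early, 3L] * (t[early] - psi[early, 4L])
  }
  out
}

#' @rdname smm_mean
#' @export
pmm_smooth_mean <- function(t, psi, v) {
  stopifnot(length(v) == 1L, is.finite(v), v >= 0)
  if (v == 0) return(pmm_abrupt_mean(t, psi))
  psi <- psi_rows(psi, length(t))
  if (any(!is.finite(psi))) stop("pmm_smooth_mean: non-finite parameter")
  p1 <- psi[, 1L]; p2 <- psi[, 2L]; p3 <- psi[, 3L]; p4 <- psi[, 4L]
  lam <- lambda_smooth(psi, v)
  out <- p1 + p2 * t                       # late line (t > psi4 + v)
  early <- t < p4
  out[early] <- lam[early] + p3[early] * t[early]
  mid <- !early & t <= p4 + v
  if (any(mid)) {
    # Hermite cubic on [psi4, psi4+v] in the local variable u = t - psi4
    u <- (t[mid] - p4[mid]) / v
    y0 <- lam[mid] + p3[mid] * p4[mid]
    y1 <- p1[mid] + p2[mid] * (p4[mid] + v)
    m0 <- p3[mid] * v
    m1 <- p2[mid] * v
    h00 <- (1 + 2 * u) * (1 - u)^2
    h10 <- u * (1 - u)^2
    h01 <- u^2 * (3 - 2 * u)
    h11 <- u^2 * (u - 1)
    out[mid] <- h00 * y0 + h10 * m0 + h01 * y1 + h11 * m1
  }
  out
}

#' Derived early-line intercept of the smooth piecewise model
#'
#' The constraint `lambda = psi1 + (psi2 - psi3) * (psi4 + v/2)` forces the
#' early line `lambda + psi3 t` and the late line `psi1 + psi2 t` to
#' intersect at the middle of the transition window, `psi4 + v/2`. `lambda`
#' is always derived, never a free parameter.
#'
#' @param psi length-4 vector or n x 4 matrix of piecewise parameters.
#' @param v non-negative transition length.
#' @return numeric vector of derived intercepts.
#' @export
lambda_smooth <- function(psi, v) {
  psi <- if (is.matrix(psi)) psi else matrix(psi, nrow = 1L)
  psi[, 1L] + (psi[, 2L] - psi[, 3L]) * (psi[, 4L] + v / 2)
}

#' Cubic transition polynomial of the smooth piecewise model
#'
#' Returns the coefficients (constant first) of the unique cubic
#' `g(t)` on the window `[psi4, psi4 + v]` satisfying the four boundary
#' conditions `g(psi4) = lambda + psi3 psi4`, `g(psi4 + v) =
#' psi1 + psi2 (psi4 + v)`, `g'(psi4) = psi3`, `g'(psi4 + v) = psi2`.
#' Two equivalent constructions are available: solving the 4x4 linear
#' system in the monomial basis (`method = "solve"`), or the two-point
#' Hermite closed form (`method = "hermite"`); they agree to machine
#' precision.
#'
#' @param psi length-4 numeric vector of piecewise parameters.
#' @param v positive transition length (`v = 0` is a singular system; use
#'   the abrupt model instead).
#' @param method `"hermite"` (default) or `"solve"`.
#' @return object of class `transition_polynomial`: a list with
#'   `coefficients` (length 4, constant first), `window` (`c(psi4, psi4+v)`)
#'   and the boundary values/slopes used.
#' @export
transition_polynomial <- function(psi, v, method = c("hermite", "solve")) {
  method <- match.arg(method)
  stopifnot(is.numeric(psi), length(psi) == 4L, all(is.finite(psi)))
  if (!is.finite(v) || v <= 0) {
    stop("transition_polynomial: the system is singular at v = 0; ",
         "branch to the abrupt model instead")
  }
  a <- psi[4L]
  b <- psi[4L] + v
  lam <- as.numeric(lambda_smooth(psi, v))
  y0 <- lam + psi[3L] * a
  y1 <- psi[1L] + psi[2L] * b
  m0 <- psi[3L]
  m1 <- psi[2L]
  if (method == "solve") {
    A <- rbind(
      c(1, a, a^2, a^3),
      c(1, b, b^2, b^3),
      c(0, 1, 2 * a, 3 * a^2),
      c(0, 1, 2 * b, 3 * b^2)
    )
    cf <- solve(A, c(y0, y1, m0, m1))
  } else {
    # Hermite form expanded to the monomial basis in s = t - a, then shifted
    h <- v
    c0 <- y0
    c1 <- m0
    c2 <- (3 * (y1 - y0) / h - 2 * m0 - m1) / h
    c3 <- (2 * (y0 - y1) / h + m0 + m1) / h^2
    # shift s = t - a: expand c0 + c1 s + c2 s^2 + c3 s^3
    cf <- c(
      c0 - c1 * a + c2 * a^2 - c3 * a^3,
      c1 - 2 * c2 * a + 3 * c3 * a^2,
      c2 - 3 * c3 * a,
      c3
    )
  }
  structure(
    list(coefficients = unname(cf), window = c(a, b),
         values = c(y0, y1), slopes = c(m0, m1), method = method),
    class = "transition_polynomial"
  )
}

#' Evaluate a transition polynomial
#' @param object a `transition_polynomial`.
#' @param t numeric vector of times.
#' @param ... unused.
#' @return numeric vector `g(t)`.
#' @export
predict.transition_polynomial <- function(object, t, ...) {
  cf <- object$coefficients
  cf[1L] + cf[2L] * t + cf[3L] * t^2 + cf[4L] * t^3
}

#' Map population parameters, covariates and random effects to
#' person-specific parameters
#'
#' Computes `psi_k = alpha_k + X_k' beta_k (+ eta_k)` for each of the four
#' structural parameters. In the sigmoidal model only the first and last
#' level carry random effects (the midpoint and Hill slope are marginal); in
#' the piecewise models all four parameters carry random effects.
#'
#' @param pop a [pop_params()] object.
#' @param X list of four numeric vectors (or `NULL`s) of covariate values,
#'   lengths matching the corresponding `beta` coefficient vectors.
#' @param eta numeric vector of random effects: length 2 (sigmoidal, on
#'   `psi1`, `psi2`) or 4 (piecewise), or `NULL` for zero.
#' @return named numeric vector `psi1..psi4` (the derived `lambda` can be
#'   obtained with [lambda_smooth()]).
#' @export
individual_parameters <- function(pop, X = NULL, eta = NULL) {
  stopifnot(inherits(pop, "pop_params"))
  re_idx <- re_indices(pop$family)
  if (is.null(eta)) eta <- numeric(length(re_idx))
  if (length(eta) != length(re_idx)) {
    stop("individual_parameters: eta must have length ", length(re_idx),
         " for family '", pop$family, "'")
  }
  psi <- numeric(4L)
  for (k in 1:4) {
    bk <- pop$beta[[k]]
    xk <- if (is.null(X)) NULL else X[[k]]
    if (length(bk)) {
      if (length(xk) != length(bk)) {
        stop("individual_parameters: covariate vector for parameter ", k,
             " has length ", length(xk), ", expected ", length(bk))
      }
      psi[k] <- pop$alpha[k] + sum(xk * bk)
    } else {
      psi[k] <- pop$alpha[k]
    }
  }
  psi[re_idx] <- psi[re_idx] + eta
  names(psi) <- paste0("psi", 1:4)
  psi
}

# recycle a length-4 psi vector into a matrix matching length(t)
psi_rows <- function(psi, n) {
  if (is.matrix(psi)) {
    if (ncol(psi) != 4L) stop("psi matrix must have 4 columns")
    if (nrow(psi) != n) stop("psi matrix must have one row per time point")
    psi
  } else {
    if (length(psi) != 4L) stop("psi must have length 4")
    if (n == 0L) return(matrix(numeric(), 0L, 4L))
    matrix(psi, nrow = n, ncol = 4L, byrow = TRUE)
  }
}
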