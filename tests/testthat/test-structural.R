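# structural mean models: exact values, continuity and the smooth
# transition construction

test_that("sigmoidal mean reproduces hand-computed values", {
  # at t = 0 the power term vanishes and f equals the last level
  expect_equal(smm_mean(0, c(1, 0.2, -5, 2)), 0.2)
  # at the midpoint half of the total change has occurred
  expect_equal(smm_mean(-5, c(1, 0, -5, 2)), 0.5)
  # direct evaluation: ratio 2, 2^2 = 4, f = 1 - 1/5
  expect_equal(smm_mean(-10, c(1, 0, -5, 2)), 0.8)
})

test_that("sigmoidal mean properties hold for random parameters", {
  set.seed(42)
  for (rep in 1:50) {
    psi <- random_smm_psi()
    expect_equal(smm_mean(0, psi), psi[2])
    expect_equal(smm_mean(psi[3], psi), (psi[1] + psi[2]) / 2)
    tt <- sort(-stats::runif(40, 0, 30))
    ft <- smm_mean(tt, psi)
    # bounded between the two levels and monotone along the half-line
    expect_true(all(ft >= min(psi[1:2]) - 1e-12 &
                      ft <= max(psi[1:2]) + 1e-12))
    expect_true(all(diff(ft) * sign(psi[2] - psi[1]) >= -1e-12))
    # asymptote: f -> first level as |t/psi3| grows, at the exact rate
    # ratio^(-psi4); the 1e-5 band applies once the Hill slope exceeds 5/6
    far <- smm_mean(psi[3] * 1e6, psi)
    expect_lt(abs(far - psi[1]),
              1.01 * abs(psi[2] - psi[1]) * 1e6^(-psi[4]) + 1e-12)
    if (psi[4] >= 1) {
      expect_lt(abs(far - psi[1]), 1e-5 * abs(psi[2] - psi[1]) + 1e-12)
    }
  }
})

test_that("sigmoidal mean rejects invalid domains", {
  expect_error(smm_mean(-1, c(1, 0, 0, 2)), "psi3")
  expect_error(smm_mean(1, c(1, 0, -5, 2)), "sign")
})

test_that("abrupt piecewise mean is continuous and piecewise linear", {
  psi <- c(0.3, -0.1, -0.02, -4)
  expect_equal(pmm_abrupt_mean(0, psi), 0.3)     # intercept at time zero
  # continuity at the changepoint from both branches
  expect_equal(pmm_abrupt_mean(-4, psi), 0.7)
  expect_equal(pmm_abrupt_mean(-4 - 1e-12, psi), 0.7, tolerance = 1e-9)
  expect_equal(pmm_abrupt_mean(-10, psi), 0.82)  # direct evaluation
  set.seed(7)
  for (rep in 1:25) {
    p <- random_pmm_psi()
    # exact continuity at the changepoint
    lhs <- p[1] + p[2] * p[4]
    expect_equal(pmm_abrupt_mean(p[4], p), lhs)
    # zero second differences on each branch, slopes psi3 then psi2
    tt <- seq(p[4] - 6, p[4] - 0.5, length.out = 9)
    expect_equal(max(abs(diff(diff(pmm_abrupt_mean(tt, p))))), 0,
                 tolerance = 1e-10)
    expect_equal(diff(pmm_abrupt_mean(c(p[4] - 2, p[4] - 1), p)), p[3])
    expect_equal(diff(pmm_abrupt_mean(c(p[4] + 1, p[4] + 2), p)), p[2])
  }
})

test_that("transition cubic matches its boundary conditions both ways", {
  set.seed(11)
  for (rep in 1:40) {
    psi <- random_pmm_psi()
    v <- stats::runif(1, 0.2, 4)
    gh <- transition_polynomial(psi, v, method = "hermite")
    gs <- transition_polynomial(psi, v, method = "solve")
    # linear solve and Hermite closed form agree to machine precision
    expect_equal(gh$coefficients, gs$coefficients, tolerance = 1e-10)
    a <- psi[4]; b <- psi[4] + v
    lam <- as.numeric(lambda_smooth(psi, v))
    # endpoint values: early line at the window start, late line at its end
    expect_equal(predict(gh, a), lam + psi[3] * a)
    expect_equal(predict(gh, b), psi[1] + psi[2] * b)
    # endpoint derivatives are the two slopes
    dg <- function(t) {
      cf <- gh$coefficients
      cf[2] + 2 * cf[3] * t + 3 * cf[4] * t^2
    }
    expect_equal(dg(a), psi[3], tolerance = 1e-8)
    expect_equal(dg(b), psi[2], tolerance = 1e-8)
  }
  # equal slopes: the cubic degenerates to the straight line itself
  psi <- c(0.3, -0.1, -0.1, -4)
  g <- transition_polynomial(psi, 2)
  tt <- seq(-4, -2, length.out = 7)
  expect_equal(predict(g, tt), 0.3 - 0.1 * tt)
  expect_error(transition_polynomial(psi, 0), "singular")
})

test_that("smooth piecewise model is C1 and collapses to the abrupt one", {
  tg <- seq(-20, 0, length.out = 1000)
  set.seed(13)
  for (rep in 1:30) {
    psi <- random_pmm_psi()
    v <- stats::runif(1, 0.5, 3)
    # outside the window the two straight lines are reproduced exactly
    lam <- as.numeric(lambda_smooth(psi, v))
    early <- tg[tg < psi[4]]
    late <- tg[tg > psi[4] + v]
    expect_equal(pmm_smooth_mean(early, psi, v), lam + psi[3] * early)
    expect_equal(pmm_smooth_mean(late, psi, v), psi[1] + psi[2] * late)
    # the lambda constraint makes the lines intersect mid-window
    tm <- psi[4] + v / 2
    expect_equal(lam + psi[3] * tm, psi[1] + psi[2] * tm)
    # C1 continuity at both window ends (relative tolerance 1e-10)
    for (tp in c(psi[4], psi[4] + v)) {
      h <- 1e-6
      val <- pmm_smooth_mean(c(tp - h, tp, tp + h), psi, v)
      scale <- max(abs(val), 1)
      expect_lt(abs(val[2] - (val[1] + val[3]) / 2) / scale, 1e-10)
      sl_l <- (val[2] - val[1]) / h
      sl_r <- (val[3] - val[2]) / h
      expect_lt(abs(sl_r - sl_l) / max(abs(sl_l), 1), 1e-4)
    }
    # v = 0 coincides with the abrupt model everywhere
    expect_identical(pmm_smooth_mean(tg, psi, 0), pmm_abrupt_mean(tg, psi))
    # and the v -> 0 limit is uniform
    expect_lt(max(abs(pmm_smooth_mean(tg, psi, 1e-8) -
                        pmm_abrupt_mean(tg, psi))), 1e-6)
  }
})

test_that("lambda is a derived quantity satisfying its constraint", {
  psi <- c(0.3, -0.1, -0.02, -4)
  v <- 1
  lam <- as.numeric(lambda_smooth(psi, v))
  expect_equal(lam, psi[1] + psi[2] * (psi[4] + v / 2) -
                 psi[3] * (psi[4] + v / 2))
})

test_that("individual parameters combine means, covariates and random effects", {
  # identity case: no covariates, no random effects
  pop <- pop_params("pmm_abrupt", alpha = c(-0.8, -0.25, -0.03, -3.5),
                    B = diag(0.1, 4), sigma = 0.1)
  expect_equal(unname(individual_parameters(pop)), pop$alpha,
               ignore_attr = TRUE)
  # sigmoidal midpoint with one covariate
  pop2 <- pop_params("smm", alpha = c(0.4, -0.6, -5, 4),
                     beta = list(numeric(), numeric(), 0.1, numeric()),
                     B = diag(0.1, 2), sigma = 0.1)
  psi <- individual_parameters(pop2, X = list(NULL, NULL, 2, NULL),
                               eta = c(0, 0))
  expect_equal(unname(psi[3]), -4.8)
  # piecewise changepoint random effect, no covariates
  psi2 <- individual_parameters(pop, eta = c(0, 0, 0, 0.5))
  expect_equal(unname(psi2[4]), -3)
  # dimension errors
  expect_error(individual_parameters(pop, eta = c(0, 0)), "length 4")
  expect_error(
    individual_parameters(pop2, X = list(NULL, NULL, c(1, 2), NULL),
                          eta = c(0, 0)),
    "covariate")
})

test_that("population-parameter container enforces its structure", {
  # piecewise covariance keeps only the slope2-slope1 off-diagonal free
  B <- matrix(0.01, 4, 4) + diag(0.1, 4)
  pop <- pop_params("pmm_abrupt", alpha = c(-1, -0.2, -0.03, -4), B = B,
                    sigma = 0.2)
  off <- pop$B; diag(off) <- 0
  expect_equal(sum(off != 0), 2L)
  expect_equal(pop$B[2, 3], 0.01)
  expect_error(pop_params("smm", alpha = c(1, 0, -4, -1), sigma = 0.1),
               "Hill")
  expect_error(pop_params("smm", alpha = c(1, 0, -4, 1), sigma = -1))
})
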