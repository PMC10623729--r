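# automatic starting values: rule constants, quintile changepoint scan,
# near-linearity detection and user overrides

test_that("near-linearity diagnostic separates linear from curved trends", {
  lin <- make_linear_data(seed = 5)
  nl <- detect_near_linearity(lin)
  expect_true(nl$near_linear)
  # an exact step in time has maximal curvature (placed off-centre:
  # a perfectly centred step is antisymmetric and its quadratic
  # coefficient vanishes identically)
  step_df <- do.call(rbind, lapply(1:30, function(i) {
    tt <- seq(-10, 0, by = 1)
    data.frame(ID = i, time = tt, y = ifelse(tt < -2, 1, 0))
  }))
  step <- long_data(step_df, id = "ID", outcome = "y", time = "time")
  expect_false(detect_near_linearity(step)$near_linear)
  # degenerate time support falls back to near-linear with a warning
  two_df <- data.frame(ID = rep(1:5, each = 2), time = rep(c(-1, 0), 5),
                       y = stats::rnorm(10))
  expect_warning(
    res <- detect_near_linearity(long_data(two_df, id = "ID", outcome = "y",
                                           time = "time")),
    "fewer than 3")
  expect_true(res$near_linear)
})

test_that("sigmoid-generated cohorts are flagged curved in most replicates", {
  hits <- 0L
  for (r in 1:20) {
    d <- simulation_design(n_subjects = 120L, family = "smm",
                           window = c(-20, 0), followup_mean = 10,
                           followup_sd = 4, followup_min = 4)
    sim <- generate_simulation_dataset(d, seed = 400L + r)
    hits <- hits + !detect_near_linearity(sim$data)$near_linear
  }
  expect_gte(hits, 18L)
})

test_that("sigmoidal initials follow the midpoint and Hill-candidate rules", {
  lin <- make_linear_data(seed = 6)
  s_lin <- smm_initials(lin)
  expect_equal(abs(unname(s_lin$values["midpoint"])), 300)
  expect_equal(sort(s_lin$hill_candidates), c(0.5, 1.05))
  sig <- make_sigmoid_data(seed = 7)
  s_sig <- smm_initials(sig)
  expect_equal(abs(unname(s_sig$values["midpoint"])), 2)
  # death-anchored timescale puts the midpoint start on the negative axis
  expect_lt(s_sig$values["midpoint"], 0)
  expect_true(s_sig$values["hill.slope"] %in% c(0.5, 1.05))
  # window means: far-from-zero window feeds the first level
  q <- stats::quantile(sig$time, c(0.05, 0.95))
  expect_equal(unname(s_sig$values["first.level"]),
               mean(sig$y[sig$time <= q[1]]))
  expect_equal(unname(s_sig$values["last.level"]),
               mean(sig$y[sig$time >= q[2]]))
  expect_error(smm_initials(long_data(
    data.frame(ID = 1:4, time = -1, y = 0), id = "ID", outcome = "y",
    time = "time")), "distinct")
})

test_that("Hill candidate selection picks the lower-RSS candidate", {
  sig <- make_sigmoid_data(seed = 8)
  s <- smm_initials(sig)
  vals <- s$values
  rss <- vapply(s$hill_candidates, function(h) {
    sum((sig$y - smm_mean(sig$time,
                          c(vals[1], vals[2], vals[3], h)))^2)
  }, numeric(1))
  expect_equal(unname(vals["hill.slope"]),
               s$hill_candidates[which.min(rss)])
})

test_that("piecewise initials locate the steepest quintile's lower bound", {
  # construct data whose steepest segment is the known final quintile
  set.seed(9)
  rows <- lapply(1:60, function(i) {
    tt <- seq(-10, 0, by = 0.5)
    y <- pmm_abrupt_mean(tt, c(-1, -0.5, -0.01, -2)) + rnorm(length(tt), 0, 0.02)
    data.frame(ID = i, time = tt, y = y)
  })
  ld <- long_data(do.call(rbind, rows), id = "ID", outcome = "y",
                  time = "time")
  s <- pmm_initials(ld)
  qb <- stats::quantile(ld$time, c(0, 0.2, 0.4, 0.6, 0.8), names = FALSE)
  # the changepoint start is one of the quintile lower bounds...
  expect_true(any(abs(s$values["changepoint"] - qb) < 1e-9))
  # ...specifically the one whose window contains the steep terminal phase
  expect_equal(unname(s$values["changepoint"]), qb[5])
  # slope starts: late (slope2) much steeper than early (slope1) here
  expect_lt(s$values["slope2"], -0.2)
  expect_gt(s$values["slope1"], -0.1)
  # last-level start is the mean outcome in the final 5% of times
  q95 <- stats::quantile(ld$time, 0.95)
  expect_equal(unname(s$values["last.level"]), mean(ld$y[ld$time >= q95]))
})

test_that("flat data give near-zero slope starts", {
  set.seed(10)
  rows <- lapply(1:40, function(i) {
    tt <- seq(-10, 0, by = 1)
    data.frame(ID = i, time = tt, y = 0.5 + rnorm(length(tt), 0, 0.01))
  })
  ld <- long_data(do.call(rbind, rows), id = "ID", outcome = "y",
                  time = "time")
  s <- suppressWarnings(pmm_initials(ld))
  expect_lt(abs(s$values["slope1"]), 0.01)
  expect_lt(abs(s$values["slope2"]), 0.01)
})

test_that("level starts are scale-equivariant and the changepoint is
           shift-equivariant", {
  sig <- make_sigmoid_data(seed = 12)
  base_pmm <- pmm_initials(sig)
  # outcome scaling scales the level starting values
  scaled <- sig
  scaled$y <- 3 * scaled$y
  s_scaled <- pmm_initials(scaled)
  expect_equal(unname(s_scaled$values["last.level"]),
               3 * unname(base_pmm$values["last.level"]))
  sm <- smm_initials(sig)
  scaled_sm <- smm_initials(scaled)
  expect_equal(unname(scaled_sm$values[c("first.level", "last.level")]),
               3 * unname(sm$values[c("first.level", "last.level")]))
  # time shift moves the changepoint start by the same amount
  shifted <- sig
  shifted$time <- shifted$time - 5
  s_shift <- pmm_initials(shifted)
  expect_equal(unname(s_shift$values["changepoint"]),
               unname(base_pmm$values["changepoint"]) - 5,
               tolerance = 1e-8)
})

test_that("user starting values override element-wise", {
  sig <- make_sigmoid_data(seed = 13)
  auto <- smm_initials(sig)
  expect_identical(resolve_start(NULL, auto), auto)
  same <- resolve_start(unname(auto$values), auto)
  expect_equal(same$values, auto$values)
  expect_true(all(same$provenance == "user override"))
  over <- resolve_start(c(1, 2, 3, 4), auto)
  expect_equal(unname(over$values), c(1, 2, 3, 4))
  partial <- resolve_start(c(NA, 9, NA, NA), auto)
  expect_equal(unname(partial$values[2]), 9)
  expect_equal(unname(partial$values[1]), unname(auto$values[1]))
  expect_equal(unname(partial$provenance[1]), unname(auto$provenance[1]))
  expect_error(resolve_start(c(1, 2, 3), auto), "length 4")
  expect_error(resolve_start(c(1, 2, 3, Inf), auto), "finite")
})
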