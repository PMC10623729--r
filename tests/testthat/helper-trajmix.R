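# shared fixtures and one-time expensive computations for the suite

# light SAEM settings for unit tests (full defaults are exercised in the
# acceptance replication study)
quick_control <- function(seed = 1L, ...) {
  saem_control(K1 = 150L, K2 = 100L, seed = seed,
               compute_is_loglik = FALSE, ...)
}

# a pure linear-trend dataset (death-anchored time, small noise)
make_linear_data <- function(n = 150L, seed = 1L, slope = 0.03,
                             intercept = 0.4, noise = 0.05) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    tt <- sort(-stats::runif(6L, 0, 20))
    data.frame(ID = i, time = tt,
               y = intercept + slope * tt + stats::rnorm(6L, 0, noise))
  })
  long_data(do.call(rbind, rows), id = "ID", outcome = "y", time = "time")
}

# strongly sigmoidal population data
make_sigmoid_data <- function(n = 150L, seed = 2L) {
  d <- simulation_design(n_subjects = n, family = "smm",
                         window = c(-20, 0), followup_mean = 10,
                         followup_sd = 4, followup_min = 4)
  generate_simulation_dataset(d, seed = seed)$data
}

# random valid parameter draws for property tests
random_smm_psi <- function() {
  c(stats::runif(1, -1, 1), stats::runif(1, -2, 0.5),
    -stats::runif(1, 1, 10), stats::runif(1, 0.5, 8))
}
random_pmm_psi <- function() {
  c(stats::runif(1, -2, 1), stats::runif(1, -0.5, 0.2),
    stats::runif(1, -0.2, 0.2), stats::runif(1, -10, -1))
}

# ---- session-level cache for expensive fits shared across test files ----
.trajmix_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .trajmix_cache)) {
    assign(key, builder(), envir = .trajmix_cache)
  }
  get(key, envir = .trajmix_cache)
}

# scaled-down replication of the performance study: sigmoidal model,
# 100 subjects, no covariates, 20 replicates, automatic initials
scaled_study <- function() {
  cache_get("scaled_study", function() {
    suppressWarnings(run_simulation_study(
      scenarios = data.frame(family = "smm", n_subjects = 100L,
                             n_covariates = 0L),
      R = 20L, initials = "automatic", seed = 20L,
      control = saem_control(compute_is_loglik = FALSE)
    ))
  })
}

# one small fitted sigmoidal model with a covariate, reused widely
small_smm_fit <- function() {
  cache_get("small_smm_fit", function() {
    dc <- generate_datacog(n_subjects = 80L, seed = 301L)
    df <- as.data.frame(dc)   # standardised columns id, time, y, ageDeath
    df$ageDeath90 <- df$ageDeath - 90
    suppressWarnings(fit_smm(df, ID = "id", outcome = "y",
                             time = "time", var_all = "ageDeath90",
                             control = quick_control(seed = 301L)))
  })
}

# one small fitted abrupt piecewise model without covariates
small_pmm_fit <- function() {
  cache_get("small_pmm_fit", function() {
    d <- simulation_design(n_subjects = 80L, family = "pmm_abrupt")
    sim <- generate_simulation_dataset(d, seed = 77L)
    suppressWarnings(saem_fit(model_spec("pmm_abrupt"), sim$data,
                              control = quick_control(seed = 77L)))
  })
}
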