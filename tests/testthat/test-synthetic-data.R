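test_that("drawn covariates reproduce the age-FA correlation and effect structure", {
  pop <- default_population()
  per <- draw_population(pop, 5000, seed = 11)
  expect_equal(cor(per$age, per$fa), -0.470, tolerance = 0.03 / 0.470)
  expect_lt(abs(cor(per$age, per$fa) + 0.470), 0.03)
  # psi is exactly the exponentiated log-linear predictor plus deviation
  expect_equal(per$psi, exp(per$lpsi), tolerance = 1e-14)
  lp <- pop$gamma[4, 1] + pop$gamma[4, 2] * per$fa + pop$gamma[4, 3] * per$age
  expect_equal(per$lpsi, lp + per$u3, tolerance = 1e-12)
})

test_that("zeroed covariate coefficients decouple effects from covariates", {
  pop <- default_population(conditional = FALSE)
  per <- draw_population(pop, 5000, seed = 3)
  for (eff in c("mu", "phi", "bt", "lpsi")) {
    expect_lt(abs(cor(per$age, per[[eff]])), 0.05)
    expect_lt(abs(cor(per$fa, per[[eff]])), 0.05)
  }
})

test_that("deviation covariance converges to the generating tau", {
  pop <- default_population(conditional = FALSE)
  pop$tau <- diag(c(0.08, 0.008, 2e-5, 0.42))
  per <- draw_population(pop, 5000, seed = 7)
  u <- as.matrix(per[, c("u0", "u1", "u2", "u3")])
  v <- apply(u, 2, var)
  expect_true(all(abs(v - diag(pop$tau)) < 0.10 * diag(pop$tau)))
  # operator-norm distance of the full covariance, relative
  d <- cov(u) - pop$tau
  expect_lt(norm(d, "2"), 0.10 * norm(pop$tau, "2"))
})

test_that("non-positive-semi-definite tau is rejected with a diagnostic", {
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(population_params(-0.9, 0.04, -0.001, -3.3, tau = bad),
               "tau")
})

test_that("zero-noise series follows the deterministic recursion exactly", {
  eff <- person_effects(mu = -0.5, phi = 0.4, bt = 0.002, psi = 1)
  eff$psi <- 0  # zero-noise limit
  s <- simulate_series(eff, 12, seed = 1, initial = "level")
  y <- numeric(12); y[1] <- -0.5
  for (t in 2:12) y[t] <- -0.5 + 0.4 * y[t - 1] + 0.002 * t
  expect_equal(s$logrt, y, tolerance = 1e-12)
})

test_that("long AR(1) series matches stationary variance and autocorrelation", {
  eff <- person_effects(mu = 0, phi = 0.5, bt = 0, psi = 1)
  s <- simulate_series(eff, 20000, seed = 42)
  expect_equal(var(s$logrt), 1 / (1 - 0.25), tolerance = 0.05)
  r1 <- cor(s$logrt[-1], s$logrt[-20000])
  expect_lt(abs(r1 - 0.5), 0.02)
})

test_that("series simulation validates inputs", {
  expect_error(person_effects(0, 0.2, 0, -1), "positive")
  eff <- person_effects(0, 0.2, 0, 1)
  expect_error(simulate_series(eff, 1), "n_trials")
})

test_that("exemplar series separate the four components", {
  ref <- person_effects(mu = -0.9, phi = 0.04, bt = -0.001, psi = exp(-3.3))
  ex <- make_exemplars(ref, seed = 5, n_trials = 300)
  expect_named(ex, c("reference", "high_mu", "high_psi", "high_bt", "high_phi"))
  expect_gt(mean(ex$high_mu$logrt), mean(ex$reference$logrt))
  detrended_sd <- function(s) sd(resid(lm(logrt ~ trial, data = s)))
  expect_gt(detrended_sd(ex$high_psi), detrended_sd(ex$reference))
  lag1 <- function(s) cor(s$logrt[-1], s$logrt[-nrow(s)])
  expect_gt(lag1(ex$high_phi), lag1(ex$reference))
})

test_that("covariate missingness is two-stage and leaves trials intact", {
  pop <- small_pop(n_trials = 2)
  ds <- simulate_dataset(pop, 2681, seed = 13, cov_obs_fraction = 1)
  out <- apply_missingness(ds, 708 / 2681, seed = 17)
  n_obs <- sum(complete.cases(out$covariates))
  # binomial 99% bounds around 708 of 2681
  bounds <- qbinom(c(0.005, 0.995), 2681, 708 / 2681)
  expect_gte(n_obs, bounds[1]); expect_lte(n_obs, bounds[2])
  expect_identical(nrow(out$trials), nrow(ds$trials))
  expect_identical(out$trials$logrt, ds$trials$logrt)
  expect_identical(apply_missingness(ds, 1, seed = 1), ds)
  expect_error(apply_missingness(ds, 0, seed = 1), "cov_obs_fraction")
})

test_that("between-person spread of series means grows with tau_mu", {
  base <- default_population(conditional = FALSE)
  spread <- sapply(c(0.02, 0.08, 0.3), function(tm) {
    pop <- base
    pop$tau[1, ] <- pop$tau[1, ] * sqrt(tm / pop$tau[1, 1])
    pop$tau[, 1] <- pop$tau[, 1] * sqrt(tm / base$tau[1, 1])
    pop$tau[1, 1] <- tm
    ds <- simulate_dataset(pop, 150, seed = 99, cov_obs_fraction = 1)
    var(tapply(ds$trials$logrt, ds$trials$person_id, mean))
  })
  expect_true(all(diff(spread) > 0))
})

test_that("written datasets round-trip through the CSV interface", {
  ds <- simulate_dataset(small_pop(5), 12, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  tr <- read_trials(paths[["trials"]])
  expect_equal(tr$logrt, ds$trials$logrt, tolerance = 1e-12)
  cv <- read_covariates(paths[["covariates"]])
  expect_equal(cv$fa, ds$covariates$fa, tolerance = 1e-12)
  expect_true(anyNA(cv$fa))  # two-stage design leaves unscanned persons NA
})
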