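test_that("summaries report mean, SD and percentile interval", {
  const <- matrix(2.5, 100, 1, dimnames = list(NULL, "c"))
  s <- summarize_draws(const)
  expect_equal(s$estimate, 2.5); expect_equal(s$sd_post, 0)
  expect_equal(s$lower, 2.5); expect_equal(s$upper, 2.5)

  set.seed(2)
  z <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "z"))
  sz <- summarize_draws(z)
  expect_lt(abs(sz$lower - (-1.96)), 0.07)
  expect_lt(abs(sz$upper - 1.96), 0.07)
  expect_equal(sz$estimate, mean(z), tolerance = 1e-14)
  expect_error(summarize_draws(matrix(numeric(0), 0, 1)), "no draws")
})

test_that("within-person standardization matches the per-person hand formula", {
  y <- c(-1.2, -0.9, -1.1, -0.8, -1.0, -0.95, -1.05, -0.85)
  phi_draw <- 0.35; bt_draw <- -0.004
  eta <- array(0, c(2, 2, 1, 4))
  eta[, , 1, 2] <- phi_draw; eta[, , 1, 3] <- bt_draw
  fit <- fake_fit(list(y), eta)
  out <- standardized_within_effects(fit)
  sy <- sd(y[-1]); slag <- sd(y[-length(y)]); st <- sd(2:length(y))
  expect_equal(unname(out$summary$estimate[1]), phi_draw * slag / sy,
               tolerance = 1e-12)
  expect_equal(unname(out$summary$estimate[2]), bt_draw * st / sy,
               tolerance = 1e-12)
  # zero coefficient maps to zero standardized effect
  eta0 <- eta; eta0[, , , 2] <- 0
  expect_equal(standardized_within_effects(fake_fit(list(y), eta0))$summary$estimate[1],
               0, tolerance = 1e-14)
  # rescaling all RTs by a constant leaves the standardized effect unchanged
  fit2 <- fake_fit(list(3 * y), eta)
  expect_equal(standardized_within_effects(fit2)$summary$estimate[1],
               out$summary$estimate[1], tolerance = 1e-12)
})

test_that("covariance converts to correlation by the stated formula", {
  expect_equal(cov_to_corr(diag(3)), diag(3))
  m <- matrix(c(4, 2, 2, 9), 2)
  expect_equal(cov_to_corr(m)[1, 2], 2 / 6, tolerance = 1e-12)
  set.seed(9)
  A <- matrix(rnorm(16), 4)
  r <- cov_to_corr(crossprod(A) + diag(4))
  expect_equal(r, t(r), tolerance = 1e-12)
  expect_true(all(abs(r) <= 1 + 1e-12))
  expect_equal(diag(r), rep(1, 4), tolerance = 1e-12)
  expect_error(cov_to_corr(matrix(c(0, 0, 0, 1), 2)), "diagonal")
})

test_that("between-person R2 compares conditional to unconditional tau per draw", {
  # same tau in both fits -> R2 = 0; conditional tau zero -> R2 = 1
  mk <- function(tau_mu) {
    draws <- array(NA_real_, c(50, 2, 3),
                   dimnames = list(NULL, NULL, c("tau_mu", "tau_mu_psi", "tau_psi")))
    draws[, , "tau_mu"] <- tau_mu
    draws[, , "tau_mu_psi"] <- 0
    draws[, , "tau_psi"] <- 0.4
    structure(list(draws = draws,
                   spec = model_spec(include_random = c(TRUE, FALSE, FALSE, TRUE))),
              class = "dsem_fit")
  }
  r0 <- r2_between(mk(0.08), mk(0.08))
  expect_equal(unname(r0$summary$estimate[1]), 0, tolerance = 1e-12)
  r1 <- r2_between(mk(0.08), mk(1e-12))
  expect_equal(unname(r1$summary$estimate[1]), 1, tolerance = 1e-6)
  # conditional variance above unconditional is flagged, clipped at zero
  r2 <- r2_between(mk(0.08), mk(0.10))
  expect_equal(unname(r2$negative_fraction[1]), 1)
  expect_equal(unname(r2$summary$estimate[1]), 0)
})

test_that("factor scores shrink toward the population mean and recover truth", {
  ds <- simulate_dataset(small_pop(25), 60, seed = 77, cov_obs_fraction = 1)
  fit <- dsem_fit(ds, model_spec(), mcmc_config(n_iter = 600, seed = 5))
  sc <- factor_scores(fit)
  expect_identical(nrow(sc), 60L)
  # shrinkage: spread of scores does not exceed the posterior mean of tau_mu
  expect_lte(var(sc$mu), mean(fit$draws[, , "tau_mu"]) * 1.05)
  expect_gt(cor(ds$truth$mu, sc$mu), 0.8)
  ffix <- dsem_fit(ds, model_spec(include_random = rep(FALSE, 4)),
                   mcmc_config(n_iter = 200, seed = 5))
  expect_error(factor_scores(ffix), "no person-level scores")
})

test_that("long precise series pin the mu score to the person's own regression", {
  pop <- small_pop(500)
  pop$tau <- diag(c(0.08, 0.002, 1e-8, 0.05))
  pop$gamma[3, 1] <- 0      # no trend
  pop$gamma[4, 1] <- -5     # small residual variance
  ds <- simulate_dataset(pop, 15, seed = 15, cov_obs_fraction = 1)
  fit <- dsem_fit(ds, model_spec(), mcmc_config(n_iter = 600, seed = 6))
  sc <- factor_scores(fit)
  ols <- sapply(fit$data$y, function(y) {
    T <- length(y)
    coef(lm(y[-1] ~ y[-T] + seq(2, T)))[1]
  })
  expect_lt(max(abs(sc$mu - ols)), 0.05)
})

test_that("posterior-SE p-values follow the normal tail formula", {
  expect_equal(p_from_posterior(0, 1), 1, tolerance = 1e-12)
  expect_equal(p_from_posterior(1.96, 1), 0.05, tolerance = 0.0005)
  expect_equal(p_from_posterior(-0.7, 0.2), p_from_posterior(0.7, 0.2),
               tolerance = 1e-14)
  expect_error(p_from_posterior(1, 0), "posterior_sd")
})

test_that("FDR adjustment reproduces the step-up hand enumeration", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  set.seed(11)
  p <- runif(20)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("standardized between-person effects scale by covariate and effect SDs", {
  # constant draws make the standardization exactly computable
  nm <- c("gamma00", "gamma01", "gamma02", "gamma10", "gamma11", "gamma12",
          "gamma20", "gamma21", "gamma22", "omega0", "omega1", "omega2",
          "tau_mu", "tau_mu_phi", "tau_mu_bt", "tau_mu_psi", "tau_phi",
          "tau_phi_bt", "tau_phi_psi", "tau_bt", "tau_bt_psi", "tau_psi",
          "exo_mean_fa", "exo_mean_age", "exo_var_fa", "exo_cov_fa_age",
          "exo_var_age")
  draws <- array(0, c(10, 2, length(nm)), dimnames = list(NULL, NULL, nm))
  draws[, , "gamma01"] <- -1.5
  draws[, , "tau_mu"] <- 0.06
  draws[, , "tau_phi"] <- 0.01; draws[, , "tau_bt"] <- 1e-5
  draws[, , "tau_psi"] <- 0.4
  draws[, , "exo_var_fa"] <- 0.03^2; draws[, , "exo_var_age"] <- 18^2
  fit <- structure(list(draws = draws,
                        data = list(cov_names = c("fa", "age")),
                        spec = model_spec(include_covariates = c(TRUE, TRUE))),
                   class = "dsem_fit")
  out <- standardized_between_effects(fit)
  s <- out$summary; rownames(s) <- s$parameter
  expl <- (-1.5)^2 * 0.03^2
  expect_equal(s["std_gamma01", "estimate"],
               -1.5 * 0.03 / sqrt(expl + 0.06), tolerance = 1e-12)
  expect_equal(s["std_gamma02", "estimate"], 0, tolerance = 1e-12)
})
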