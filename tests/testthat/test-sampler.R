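# Unit-level sampler checks on small cohorts; the heavier recovery, DIC and
# calibration properties live in test-acceptance.R.

test_that("identical seeds reproduce identical draws", {
  ds <- simulate_dataset(small_pop(12), 20, seed = 3, cov_obs_fraction = 1)
  cfg <- mcmc_config(n_iter = 300, seed = 5)
  f1 <- dsem_fit(ds, model_spec(), cfg)
  f2 <- dsem_fit(ds, model_spec(), cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- dsem_fit(ds, model_spec(), mcmc_config(n_iter = 300, seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("fixed-effects fit recovers pooled-regression truth without random effects", {
  pop <- default_population(conditional = FALSE)
  pop$tau <- matrix(0, 4, 4)
  ds <- simulate_dataset(pop, 200, seed = 9, cov_obs_fraction = 1)
  fit <- dsem_fit(ds, model_spec(include_random = rep(FALSE, 4)),
                  mcmc_config(n_iter = 1000, seed = 2))
  s <- summarize_draws(fit); rownames(s) <- s$parameter
  truth <- c(gamma00 = pop$gamma[1, 1], gamma10 = pop$gamma[2, 1],
             gamma20 = pop$gamma[3, 1])
  for (p in names(truth)) {
    expect_lt(abs(s[p, "estimate"] - truth[p]) / s[p, "sd_post"], 3)
  }
  # independent cross-check: pooled maximum-likelihood AR regression
  dt <- ds$trials
  dt$ylag <- ave(dt$logrt, dt$person_id, FUN = function(y) c(NA, head(y, -1)))
  ml <- coef(lm(logrt ~ ylag + trial, data = dt))
  expect_lt(abs(s["gamma00", "estimate"] - ml[1]), 3 * s["gamma00", "sd_post"])
  expect_lt(abs(s["gamma10", "estimate"] - ml[2]), 3 * s["gamma10", "sd_post"])
  expect_lt(abs(s["gamma20", "estimate"] - ml[3]), 3 * s["gamma20", "sd_post"])
})

test_that("with the data removed the posterior reproduces the prior", {
  trials <- data.frame(person_id = rep(1:5, each = 3), trial = rep(1:3, 5),
                       logrt = NA_real_)
  fit <- dsem_fit(trials, model_spec(include_random = rep(FALSE, 4)),
                  mcmc_config(n_iter = 10100, n_burn = 100, seed = 8),
                  dsem_prior(gamma_mean = 0, gamma_sd = 10))
  g <- as.vector(fit$draws[, , "gamma00"])
  ks <- suppressWarnings(ks.test(g, "pnorm", 0, 10)$statistic)
  expect_lt(ks, 0.1)
  # random effects have no proper prior without data
  expect_error(dsem_fit(trials, model_spec(),
                        mcmc_config(n_iter = 200, seed = 1)),
               "fixed-effects")
})

test_that("tau draws stay positive definite and psi draws positive", {
  ds <- simulate_dataset(small_pop(15), 30, seed = 21, cov_obs_fraction = 1)
  fit <- dsem_fit(ds, model_spec(), mcmc_config(n_iter = 400, seed = 3))
  m <- dsemrt:::flat_draws(fit)
  lab <- c("mu", "phi", "bt", "psi")
  idx <- sample.int(nrow(m), 50)
  for (r in idx) {
    tau <- diag(4)
    for (a in 1:4) for (b in a:4) {
      nm <- if (a == b) paste0("tau_", lab[a]) else paste0("tau_", lab[a], "_", lab[b])
      tau[a, b] <- tau[b, a] <- m[r, nm]
    }
    expect_gt(min(eigen(tau, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_true(all(is.finite(fit$eta[, , , 4])))
})

test_that("missing trials and missing covariates are imputed, not dropped", {
  ds <- simulate_dataset(small_pop(20, conditional = TRUE), 40, seed = 31,
                         cov_obs_fraction = 0.5)
  idx <- sample(seq_len(nrow(ds$trials)), 60)
  ds$trials$logrt[idx] <- NA
  fit <- dsem_fit(ds, model_spec(include_covariates = c(TRUE, TRUE)),
                  mcmc_config(n_iter = 400, seed = 4))
  s <- summarize_draws(fit)
  expect_true(all(is.finite(s$estimate)))
  expect_identical(length(fit$data$ids), 40L)  # nobody listwise-deleted
})

test_that("fit validates degenerate and unsupported inputs", {
  ds <- simulate_dataset(small_pop(10), 15, seed = 2, cov_obs_fraction = 1)
  const <- ds
  const$trials$logrt[const$trials$person_id == 1] <- -0.9
  expect_error(dsem_fit(const, model_spec(),
                        mcmc_config(n_iter = 100, seed = 1)),
               "all-constant")
  expect_error(dsem_fit(ds, model_spec(lag_centering = "latent_centered"),
                        mcmc_config(n_iter = 100, seed = 1)),
               "raw_lag")
  expect_error(dsem_fit(ds, model_spec(include_random = c(TRUE, FALSE, FALSE, TRUE),
                                       include_covariates = c(TRUE, FALSE)),
                        mcmc_config(n_iter = 100, seed = 1)),
               "random effects")
  few <- ds
  few$trials <- few$trials[few$trials$person_id <= 3, ]
  expect_error(dsem_fit(few, model_spec(), mcmc_config(n_iter = 100, seed = 1)),
               "too few persons")
})

test_that("few trials per person triggers the weak-identification warning", {
  pop <- small_pop(3)
  ds <- simulate_dataset(pop, 30, seed = 5, cov_obs_fraction = 1)
  expect_warning(dsem_fit(ds, model_spec(), mcmc_config(n_iter = 200, seed = 1)),
                 "weakly identified")
})

test_that("constrained specs estimate only the requested random effects", {
  ds <- simulate_dataset(small_pop(15), 25, seed = 41, cov_obs_fraction = 1)
  fit <- dsem_fit(ds, model_spec(include_random = c(TRUE, FALSE, FALSE, TRUE)),
                  mcmc_config(n_iter = 300, seed = 2))
  nm <- dimnames(fit$draws)[[3]]
  expect_true(all(c("tau_mu", "tau_psi", "tau_mu_psi") %in% nm))
  expect_false(any(grepl("tau_phi|tau_bt", nm)))
  # deactivated components still enter as fixed effects
  expect_true(all(c("gamma10", "gamma20") %in% nm))
})
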