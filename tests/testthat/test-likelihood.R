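test_that("zero-residual two-trial series gives the normal constant", {
  eff <- person_effects(mu = 0.3, phi = 0.5, bt = 0.01, psi = 1)
  y1 <- -0.2
  y2 <- 0.3 + 0.5 * y1 + 0.01 * 2
  s <- data.frame(person_id = 1, trial = 1:2, logrt = c(y1, y2))
  expect_equal(conditional_loglik(s, eff), -0.5 * log(2 * pi),
               tolerance = 1e-12)
})

test_that("without dynamics the likelihood reduces to iid normals", {
  set.seed(4)
  y <- rnorm(15, -0.9, 0.2)
  s <- data.frame(person_id = 1, trial = 1:15, logrt = y)
  eff <- person_effects(mu = -0.85, phi = 0, bt = 0, psi = 0.05)
  expect_equal(conditional_loglik(s, eff),
               sum(dnorm(y[-1], -0.85, sqrt(0.05), log = TRUE)),
               tolerance = 1e-12)
})

test_that("likelihood matches the brute-force density oracle", {
  set.seed(8)
  for (rep in 1:100) {
    eff <- random_effects()
    y <- as.numeric(arima.sim(list(ar = eff$phi), 10)) * 0.1 + eff$mu
    s <- data.frame(person_id = 1, trial = 1:10, logrt = y)
    expect_equal(conditional_loglik(s, eff),
                 brute_force_loglik(y, 1:10, eff$mu, eff$phi, eff$bt, eff$psi),
                 tolerance = 1e-10)
  }
})

test_that("stationary initial condition adds the initial-state density", {
  eff <- person_effects(mu = -0.9, phi = 0.4, bt = 0.001, psi = 0.04)
  y <- c(-1.4, -1.5, -1.45)
  s <- data.frame(person_id = 1, trial = 1:3, logrt = y)
  base <- conditional_loglik(s, eff)
  full <- conditional_loglik(s, eff,
                             model_spec(initial_condition = "stationary"))
  m1 <- (eff$mu + eff$bt) / (1 - eff$phi)
  v1 <- eff$psi / (1 - eff$phi^2)
  expect_equal(full - base, dnorm(y[1], m1, sqrt(v1), log = TRUE),
               tolerance = 1e-12)
  eff$phi <- 1.2
  expect_error(conditional_loglik(s, eff,
                                  model_spec(initial_condition = "stationary")),
               "phi")
})

test_that("likelihood validates inputs and handles missing trials by skipping", {
  eff <- person_effects(-0.9, 0.1, 0, 0.04)
  s <- data.frame(person_id = 1, trial = 1:5,
                  logrt = c(-1, NA, -0.8, -0.9, -1.1))
  ll <- conditional_loglik(s, eff)
  # terms 2 and 3 drop (outcome or lag missing); terms 4, 5 remain
  r4 <- s$logrt[4] - (eff$mu + eff$phi * s$logrt[3] + eff$bt * 4)
  r5 <- s$logrt[5] - (eff$mu + eff$phi * s$logrt[4] + eff$bt * 5)
  expect_equal(ll, sum(dnorm(c(r4, r5), 0, 0.2, log = TRUE)), tolerance = 1e-12)
  bad <- eff; bad$psi <- -1
  expect_error(conditional_loglik(s, bad), "psi")
  short <- data.frame(person_id = 1, trial = 1:3, logrt = c(-1, NA, NA))
  expect_error(conditional_loglik(short, eff), "too short")
})

test_that("log-density is additive over persons and permutation invariant", {
  set.seed(12)
  series <- lapply(1:4, function(i) {
    data.frame(person_id = i, trial = 1:8, logrt = rnorm(8, -1, 0.3))
  })
  effs <- replicate(4, random_effects(), simplify = FALSE)
  total <- sum(mapply(function(s, e) conditional_loglik(s, e), series, effs))
  perm <- sample(4)
  total_p <- sum(mapply(function(s, e) conditional_loglik(s, e),
                        series[perm], effs[perm]))
  expect_equal(total, total_p, tolerance = 1e-12)
})

test_that("latent centering is shift-equivariant, raw lag is not", {
  set.seed(3)
  y <- rnorm(10, -1, 0.3)
  eff <- person_effects(mu = -1, phi = 0.3, bt = 0.002, psi = 0.05)
  s0 <- data.frame(person_id = 1, trial = 1:10, logrt = y)
  s1 <- data.frame(person_id = 1, trial = 1:10, logrt = y + 5)
  eff5 <- eff; eff5$mu <- eff$mu + 5
  cen <- model_spec(lag_centering = "latent_centered")
  expect_equal(conditional_loglik(s0, eff, cen),
               conditional_loglik(s1, eff5, cen), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(conditional_loglik(s0, eff),
                                conditional_loglik(s1, eff5))))
})

test_that("log-density diverges to -Inf as psi shrinks under nonzero residual", {
  s <- data.frame(person_id = 1, trial = 1:3, logrt = c(-1, -0.8, -1.2))
  eff <- person_effects(-0.9, 0, 0, 1)
  lls <- sapply(10^seq(-2, -10, by = -2), function(p) {
    e <- eff; e$psi <- p
    conditional_loglik(s, e)
  })
  expect_true(all(diff(lls) < 0))
  expect_lt(lls[length(lls)], -1e6)
})

test_that("MVN deviation prior matches the explicit-formula oracle", {
  expect_equal(random_effect_logprior(rep(0, 4), diag(4)), -2 * log(2 * pi),
               tolerance = 1e-12)
  set.seed(5)
  u <- rnorm(4)
  expect_equal(random_effect_logprior(u, diag(4)),
               sum(dnorm(u, log = TRUE)), tolerance = 1e-12)
  A <- matrix(rnorm(16), 4); tau <- crossprod(A) + diag(4)
  # independent oracle: explicit inverse and determinant
  oracle <- -0.5 * (4 * log(2 * pi) + log(det(tau)) +
                      drop(t(u) %*% solve(tau) %*% u))
  expect_equal(random_effect_logprior(u, tau), oracle, tolerance = 1e-10)
  expect_error(random_effect_logprior(u, diag(3)), "dimension")
})

test_that("level-2 prediction evaluates the stated regressions", {
  g0 <- matrix(c(-0.9, 0, 0, 0.04, 0, 0, -0.001, 0, 0, -3.3, 0, 0),
               4, 3, byrow = TRUE)
  p <- level2_predict(list(fa = 0.8, age = 70), g0)
  expect_equal(unlist(p), c(mu = -0.9, phi = 0.04, bt = -0.001,
                            psi = exp(-3.3)), tolerance = 1e-12)
  g1 <- g0; g1[4, ] <- c(0, 1, 0)
  expect_equal(level2_predict(list(fa = 0.5, age = 0), g1)$psi, exp(0.5),
               tolerance = 1e-12)
  # log-linearity: an increment on the log scale multiplies psi
  g2 <- g1; g2[4, 3] <- 0.01
  p1 <- level2_predict(list(fa = 0.5, age = 30), g1)$psi
  p2 <- level2_predict(list(fa = 0.5, age = 30), g2)$psi
  expect_equal(p2 / p1, exp(0.01 * 30), tolerance = 1e-12)
})
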