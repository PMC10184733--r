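#' Population parameters for the synthetic reaction-time cohort
#'
#' Bundles everything the generative model needs: fixed intercepts for the
#' four person-level components (mean log-RT `mu`, lag-1 autoregression `phi`,
#' per-trial trend `bt`, and the log residual variance `lpsi`), the
#' white-matter FA and age regression coefficients for each component, the
#' 4x4 residual covariance `tau` of the person deviations
#' (u0, u1, u2, u3), the bivariate distribution of the (age, FA) covariates,
#' the number of trials per person, and the fraction of persons with observed
#' covariates (the two-stage design: everyone contributes behavior, only a
#' subset is scanned).
#'
#' The residual variance is log-linear: `psi_i = exp(omega0 + omega1*fa +
#' omega2*age + u3_i)`, so `psi_i` is strictly positive by construction.
#'
#' @param gamma00,gamma10,gamma20 fixed intercepts of `mu` (log-seconds),
#'   `phi` (unitless) and `bt` (log-seconds per trial).
#' @param omega0 fixed intercept of the log residual variance.
#' @param gamma01,gamma11,gamma21,omega1 FA coefficients for the four
#'   components (per unit FA).
#' @param gamma02,gamma12,gamma22,omega2 age coefficients (per year).
#' @param tau 4x4 symmetric positive semi-definite residual covariance of
#'   the person deviations, ordered (mu, phi, bt, lpsi).
#' @param cov_means length-2 mean vector of (age, fa).
#' @param cov_cov 2x2 positive-definite covariance of (age, fa).
#' @param n_trials trials per person (>= 2).
#' @param cov_obs_fraction fraction of persons with observed covariates,
#'   in (0, 1].
#' @return an object of class `dsem_population`.
#' @seealso [default_population()] for study-calibrated defaults,
#'   [draw_population()], [simulate_dataset()].
#' @export
population_params <- function(gamma00, gamma10, gamma20, omega0,
                              gamma01 = 0, gamma11 = 0, gamma21 = 0, omega1 = 0,
                              gamma02 = 0, gamma12 = 0, gamma22 = 0, omega2 = 0,
                              tau,
                              cov_means = c(age = 54, fa = 0.40),
                              cov_cov = matrix(c(18^2, -0.470 * 18 * 0.03,
                                                 -0.470 * 18 * 0.03, 0.03^2), 2, 2),
                              n_trials = 50,
                              cov_obs_fraction = 708 / 2681) {
  tau <- as.matrix(tau)
  if (!isTRUE(all.equal(dim(tau), c(4L, 4L))))
    stop("tau must be a 4x4 matrix")
  if (max(abs(tau - t(tau))) > 1e-10)
    stop("tau must be symmetric")
  ev <- eigen(tau, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("tau is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  cov_cov <- as.matrix(cov_cov)
  if (min(eigen(cov_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("cov_cov must be positive definite")
  if (n_trials < 2) stop("n_trials must be >= 2")
  if (cov_obs_fraction <= 0 || cov_obs_fraction > 1)
    stop("cov_obs_fraction must be in (0, 1]")
  dimnames(tau) <- list(.comp_names, .comp_names)
  structure(list(
    gamma = matrix(c(gamma00, gamma01, gamma02,
                     gamma10, gamma11, gamma12,
                     gamma20, gamma21, gamma22,
                     omega0, omega1, omega2),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(.comp_names, c("intercept", "fa", "age"))),
    tau = tau,
    cov_means = c(age = unname(cov_means[1]), fa = unname(cov_means[2])),
    cov_cov = cov_cov,
    n_trials = as.integer(n_trials),
    cov_obs_fraction = cov_obs_fraction
  ), class = "dsem_population")
}

#' Study-calibrated default population
#'
#' Default generating values for the synthetic cohort. Component means
#' (mean log-RT -0.908, autoregression 0.036, trend -0.001, log residual
#' variance -3.292) and the between-person variances
#' (0.083, 0.008, 1.9e-5, 0.424) follow the unconditional estimates of a
#' large lifespan simple-RT study; covariate effects are back-transformed
#' from the standardized FA and age effects reported there
#' (e.g. -0.149 and 0.351 on the mean, -0.197 and 0.272 on log variance)
#' using age SD 18 years and tract-FA SD 0.03, and the residual covariance
#' `tau` is the total variance deflated by the reported between-person
#' R-squared per component. Residual correlations follow the reported
#' qualitative pattern (mu, phi, lpsi mutually positive, all negative with
#' the trend; mu-lpsi residual correlation 0.263). Intercepts are chosen so
#' the population means of the four components land on the unconditional
#' values at the covariate means. Age-FA correlation is -0.470; 50 trials
#' per person; covariates observed for 708/2681 of persons.
#'
#' @param conditional if `FALSE`, all covariate coefficients are zero and
#'   `tau` carries the total (unconditional) between-person covariance.
#' @return a `dsem_population` object.
#' @export
default_population <- function(conditional = TRUE) {
  comp_mean <- c(mu = -0.908, phi = 0.036, bt = -0.001, lpsi = -3.292)
  tau_total <- c(mu = 0.083, phi = 0.008, bt = 1.9e-5, lpsi = 0.424)
  r2        <- c(mu = 0.201, phi = 0.010, bt = 0.012, lpsi = 0.169)
  std_fa    <- c(mu = -0.149, phi = -0.085, bt = 0.042, lpsi = -0.197)
  std_age   <- c(mu =  0.351, phi =  0.012, bt = -0.072, lpsi = 0.272)
  sd_age <- 18; sd_fa <- 0.03
  m_age <- 54; m_fa <- 0.40

  sd_tot <- sqrt(tau_total)
  if (conditional) {
    b_fa  <- std_fa  * sd_tot / sd_fa
    b_age <- std_age * sd_tot / sd_age
    tau_d <- tau_total * (1 - r2)
  } else {
    b_fa <- b_age <- rep(0, 4)
    tau_d <- tau_total
  }
  # residual correlations: chosen once, within the reported sign pattern
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.20   # mu-phi
  R[1, 3] <- R[3, 1] <- -0.20  # mu-bt
  R[1, 4] <- R[4, 1] <- if (conditional) 0.263 else 0.397  # mu-lpsi
  R[2, 3] <- R[3, 2] <- -0.20  # phi-bt
  R[2, 4] <- R[4, 2] <- 0.20   # phi-lpsi
  R[3, 4] <- R[4, 3] <- -0.20  # bt-lpsi
  tau <- diag(sqrt(tau_d)) %*% R %*% diag(sqrt(tau_d))
  icpt <- comp_mean - b_fa * m_fa - b_age * m_age

  population_params(
    gamma00 = icpt[1], gamma10 = icpt[2], gamma20 = icpt[3], omega0 = icpt[4],
    gamma01 = b_fa[1], gamma11 = b_fa[2], gamma21 = b_fa[3], omega1 = b_fa[4],
    gamma02 = b_age[1], gamma12 = b_age[2], gamma22 = b_age[3], omega2 = b_age[4],
    tau = tau,
    cov_means = c(age = m_age, fa = m_fa),
    cov_cov = matrix(c(sd_age^2, -0.470 * sd_age * sd_fa,
                       -0.470 * sd_age * sd_fa, sd_fa^2), 2, 2),
    n_trials = 50,
    cov_obs_fraction = 708 / 2681
  )
}

#' Person-specific effects
#'
#' Container for one person's four dynamic components. `psi` is the residual
#' variance on the natural scale and always satisfies
#' `psi == exp(lpsi)` where `lpsi` is the log-linear predictor plus `u[4]`.
#'
#' @param mu mean log-RT (log-seconds).
#' @param phi lag-1 autoregressive coefficient.
#' @param bt per-trial linear trend (log-seconds/trial).
#' @param psi residual variance (strictly positive).
#' @param u optional length-4 deviation vector (u0..u3).
#' @return a `person_effects` object.
#' @export
person_effects <- function(mu, phi, bt, psi, u = rep(0, 4)) {
  if (!is.finite(psi) || psi <= 0) stop("psi must be strictly positive")
  structure(list(mu = mu, phi = phi, bt = bt, psi = psi,
                 lpsi = log(psi), u = u),
            class = "person_effects")
}
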