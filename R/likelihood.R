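#' Model specification
#'
#' Controls which of the four person-level components carry random effects,
#' which covariate blocks enter the level-2 regressions, how the lagged
#' outcome is parameterized, and how the first trial is treated.
#'
#' With `lag_centering = "raw_lag"` the within-person model regresses on the
#' raw previous outcome, `y_t = mu + phi*y_(t-1) + bt*t + e_t`. With
#' `"latent_centered"` the lag and trend are removed before the
#' autoregression, `y_t - mu - bt*t = phi*(y_(t-1) - mu - bt*(t-1)) + e_t`,
#' which makes residuals invariant to a common shift of the series and its
#' mean; the fitted intercept then has a different interpretation.
#'
#' @param include_random logical length-4, random effects for
#'   (mu, phi, bt, psi). The mean intercept is always present as a fixed
#'   effect regardless.
#' @param include_covariates logical length-2, (fa/WM block, age block).
#' @param lag_centering `"raw_lag"` (default) or `"latent_centered"`.
#' @param initial_condition `"condition_on_first"` (default; trial 1 enters
#'   only as a predictor) or `"stationary"` (adds the initial-state density).
#' @return a `model_spec` object.
#' @export
model_spec <- function(include_random = c(TRUE, TRUE, TRUE, TRUE),
                       include_covariates = c(FALSE, FALSE),
                       lag_centering = c("raw_lag", "latent_centered"),
                       initial_condition = c("condition_on_first", "stationary")) {
  lag_centering <- match.arg(lag_centering)
  initial_condition <- match.arg(initial_condition)
  include_random <- rep_len(as.logical(include_random), 4L)
  include_covariates <- rep_len(as.logical(include_covariates), 2L)
  structure(list(include_random = setNames(include_random, .comp_names),
                 include_covariates = setNames(include_covariates,
                                               c("fa", "age")),
                 lag_centering = lag_centering,
                 initial_condition = initial_condition),
            class = "model_spec")
}

# Per-trial residuals for t >= 2 under either lag parameterization.
series_residuals <- function(y, trials, effects, lag_centering = "raw_lag") {
  t2 <- seq.int(2L, length(y))
  if (lag_centering == "raw_lag") {
    y[t2] - (effects$mu + effects$phi * y[t2 - 1L] + effects$bt * trials[t2])
  } else {
    d <- y - effects$mu - effects$bt * trials
    d[t2] - effects$phi * d[t2 - 1L]
  }
}

#' Within-person conditional log-likelihood
#'
#' Evaluates the exact log-density of one person's ordered log-RT series
#' under the within-person model, summed over trials t >= 2:
#' `sum log N(y_t | m_t, psi)` with `m_t` given by the lag parameterization
#' of `spec`. Under `initial_condition = "stationary"` the density of the
#' first trial, `N((mu + bt)/(1 - phi), psi/(1 - phi^2))`, is added
#' (requires `|phi| < 1`). Trials where the outcome or its lag is missing
#' are skipped; imputation is the sampler's job, not the likelihood's.
#'
#' @param series a data frame with columns `trial`, `logrt` (a
#'   `trial_series`).
#' @param effects a `person_effects`.
#' @param spec a `model_spec`.
#' @return the log-density (scalar).
#' @export
conditional_loglik <- function(series, effects, spec = model_spec()) {
  psi <- effects$psi
  if (!is.finite(psi) || psi <= 0) stop("psi must be strictly positive")
  psi <- max(psi, 1e-12)
  y <- series$logrt
  trials <- series$trial
  if (is.unsorted(trials, strictly = TRUE))
    stop("trial indices must be strictly increasing")
  if (sum(is.finite(y)) < 2) stop("series too short: need >= 2 non-missing trials")
  r <- series_residuals(y, trials, effects, spec$lag_centering)
  ok <- is.finite(r)
  ll <- sum(dnorm(r[ok], 0, sqrt(psi), log = TRUE))
  if (spec$initial_condition == "stationary") {
    if (abs(effects$phi) >= 1)
      stop("stationary initial condition requires |phi| < 1")
    m1 <- (effects$mu + effects$bt * trials[1]) / (1 - effects$phi)
    v1 <- psi / (1 - effects$phi^2)
    if (is.finite(y[1])) ll <- ll + dnorm(y[1], m1, sqrt(v1), log = TRUE)
  }
  ll
}

#' Multivariate-normal log-prior of a person deviation vector
#'
#' Log-density of `u` under MVN(0, tau), evaluated by Cholesky (with an
#' eigenvalue fallback for semi-definite tau).
#'
#' @param u numeric deviation vector.
#' @param tau covariance matrix matching `length(u)`.
#' @return the log-density.
#' @export
random_effect_logprior <- function(u, tau) {
  tau <- as.matrix(tau)
  d <- length(u)
  if (!all(dim(tau) == d)) stop("dimension mismatch between u and tau")
  ch <- tryCatch(chol(tau), error = function(e) NULL)
  if (is.null(ch)) stop("tau is not positive definite")
  z <- backsolve(ch, u, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Covariate-implied person effects (level-2 prediction)
#'
#' Evaluates the level-2 regressions at given covariate values with all
#' person deviations set to zero:
#' `mu = gamma00 + gamma01*fa + gamma02*age`, likewise for `phi` and the
#' trend, and `psi = exp(omega0 + omega1*fa + omega2*age)`.
#'
#' @param covariates data frame (or list) with elements `fa` and/or `age`;
#'   a covariate may be omitted when its coefficients are zero. `NA`
#'   covariates yield `NA` predictions (in the sampler they are imputed
#'   through the joint exogenous model instead).
#' @param gamma 4x3 coefficient matrix, rows (mu, phi, bt, lpsi), columns
#'   (intercept, fa, age), as in [population_params()].
#' @return data frame with columns `mu`, `phi`, `bt`, `psi`.
#' @export
level2_predict <- function(covariates, gamma) {
  gamma <- as.matrix(gamma)
  stopifnot(all(dim(gamma) == c(4L, 3L)))
  fa <- covariates$fa %||% 0
  age <- covariates$age %||% 0
  n <- max(length(fa), length(age), 1L)
  X <- cbind(1, rep_len(fa, n), rep_len(age, n))
  eta <- X %*% t(gamma)
  data.frame(mu = eta[, 1], phi = eta[, 2], bt = eta[, 3], psi = exp(eta[, 4]))
}
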