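#' Draw a synthetic population of persons
#'
#' Samples (age, FA) covariates from the configured bivariate normal, person
#' deviations `u` from MVN(0, tau), and assembles the four person-specific
#' components from the level-2 regressions:
#' `mu_i = gamma00 + gamma01*fa + gamma02*age + u0`, similarly for `phi` and
#' the trend, and `psi_i = exp(omega0 + omega1*fa + omega2*age + u3)`.
#'
#' @param pop a `dsem_population`.
#' @param n_persons number of persons (>= 2).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return data frame with one row per person: `person_id`, `age`, `fa`,
#'   true effects `mu`, `phi`, `bt`, `psi`, `lpsi`, and deviations `u0`..`u3`.
#' @export
draw_population <- function(pop, n_persons, seed = 1L) {
  stopifnot(inherits(pop, "dsem_population"))
  if (n_persons < 2) stop("n_persons must be >= 2")
  set.seed(seed)
  xy <- rmvn_chol(n_persons, pop$cov_means, pop$cov_cov)
  age <- xy[, 1]; fa <- xy[, 2]
  u <- rmvn_chol(n_persons, rep(0, 4), pop$tau)
  X <- cbind(1, fa, age)                       # matches gamma column order
  eta <- X %*% t(pop$gamma) + u                # n x 4, (mu, phi, bt, lpsi)
  data.frame(
    person_id = seq_len(n_persons),
    age = age, fa = fa,
    mu = eta[, 1], phi = eta[, 2], bt = eta[, 3],
    psi = exp(eta[, 4]), lpsi = eta[, 4],
    u0 = u[, 1], u1 = u[, 2], u2 = u[, 3], u3 = u[, 4]
  )
}

#' Simulate one person's trial series
#'
#' Generates log reaction times from the within-person model
#' `y_t = mu + phi * y_(t-1) + bt * t + e_t`, `e_t ~ N(0, psi)` for t >= 2.
#' The first trial is drawn from the local stationary distribution when
#' `initial = "stationary"` and `|phi| < 1` (mean `(mu + bt)/(1 - phi)`,
#' variance `psi/(1 - phi^2)`), otherwise from `N(mu, psi)`; with
#' `initial = "level"` it is always `N(mu, psi)`. A linear trend makes the
#' process non-stationary, so the "stationary" draw uses the level implied
#' at trial 1; this keeps short series from starting systematically off
#' their own regime.
#'
#' @param effects a `person_effects` object (psi = 0 is allowed and yields
#'   the deterministic recursion).
#' @param n_trials number of trials (>= 2).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param initial `"stationary"` or `"level"`.
#' @param person_id identifier attached to the output.
#' @return data frame `person_id`, `trial`, `logrt` (class `trial_series`).
#' @export
simulate_series <- function(effects, n_trials, seed = NULL,
                            initial = c("stationary", "level"),
                            person_id = 1L) {
  initial <- match.arg(initial)
  if (n_trials < 2) stop("n_trials must be >= 2")
  psi <- if (inherits(effects, "person_effects")) effects$psi else effects[["psi"]]
  mu <- effects$mu; phi <- effects$phi; bt <- effects$bt
  if (!is.finite(psi) || psi < 0) stop("psi must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  z <- rnorm(n_trials)
  s <- sqrt(psi)
  y <- numeric(n_trials)
  if (initial == "stationary" && abs(phi) < 1) {
    y[1] <- (mu + bt) / (1 - phi) + z[1] * s / sqrt(1 - phi^2)
  } else {
    y[1] <- mu + z[1] * s
  }
  for (t in 2:n_trials)
    y[t] <- mu + phi * y[t - 1] + bt * t + s * z[t]
  out <- data.frame(person_id = person_id, trial = seq_len(n_trials), logrt = y)
  class(out) <- c("trial_series", "data.frame")
  out
}

#' Exemplar time-series contrasting the four components
#'
#' Produces five series from a reference person: the reference itself plus
#' one variant per component where that component alone is raised by
#' `offset_sd` of its between-person SD (the log-variance for `psi`). All
#' five reuse the same innovation seed so differences are attributable to
#' the altered component, not to noise.
#'
#' @param reference a `person_effects` object.
#' @param seed integer seed shared by all five series.
#' @param n_trials trials per series.
#' @param offset_sd how many SDs to add to the targeted component.
#' @param comp_sd length-4 SDs of (mu, phi, bt, lpsi); defaults to the
#'   square roots of the default population's total variances.
#' @return named list of `trial_series`: reference, high_mu, high_psi,
#'   high_bt, high_phi.
#' @export
make_exemplars <- function(reference, seed = 1L, n_trials = 200L,
                           offset_sd = 2,
                           comp_sd = sqrt(c(0.083, 0.008, 1.9e-5, 0.424))) {
  stopifnot(inherits(reference, "person_effects"))
  bump <- function(which) {
    e <- reference
    if (which == "mu")   e$mu  <- e$mu + offset_sd * comp_sd[1]
    if (which == "phi")  e$phi <- e$phi + offset_sd * comp_sd[2]
    if (which == "bt")   e$bt  <- e$bt + offset_sd * comp_sd[3]
    if (which == "psi") {
      e$lpsi <- e$lpsi + offset_sd * comp_sd[4]
      e$psi <- exp(e$lpsi)
    }
    e
  }
  sim <- function(e, id) simulate_series(e, n_trials, seed = seed,
                                         person_id = id)
  list(reference = sim(reference, 1L),
       high_mu   = sim(bump("mu"), 2L),
       high_psi  = sim(bump("psi"), 3L),
       high_bt   = sim(bump("bt"), 4L),
       high_phi  = sim(bump("phi"), 5L))
}

#' Apply two-stage covariate missingness
#'
#' Emulates a design where everyone contributes trial data but only a random
#' subset has covariates measured: each person's covariates are kept with
#' probability `cov_obs_fraction`, independently (missing completely at
#' random). Trial rows are never touched.
#'
#' @param dataset a `dsem_data` object (see [simulate_dataset()]).
#' @param cov_obs_fraction keep probability in (0, 1].
#' @param seed integer seed.
#' @return the dataset with covariate columns set `NA` for unobserved persons.
#' @export
apply_missingness <- function(dataset, cov_obs_fraction, seed = 1L) {
  stopifnot(inherits(dataset, "dsem_data"))
  if (cov_obs_fraction <= 0 || cov_obs_fraction > 1)
    stop("cov_obs_fraction must be in (0, 1]")
  if (cov_obs_fraction == 1) return(dataset)
  set.seed(seed)
  n <- nrow(dataset$covariates)
  keep <- rbinom(n, 1L, cov_obs_fraction) == 1L
  covcols <- setdiff(names(dataset$covariates), "person_id")
  dataset$covariates[!keep, covcols] <- NA_real_
  dataset
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: draws the population, simulates every person's trial
#' series, and applies the two-stage covariate missingness. The ground-truth
#' person effects are kept alongside for recovery checks.
#'
#' @param pop a `dsem_population` (default [default_population()]).
#' @param n_persons cohort size.
#' @param seed integer seed governing all stages.
#' @param cov_obs_fraction overrides the population's observed fraction if
#'   not `NULL`.
#' @param initial initial-condition rule passed to [simulate_series()].
#' @return a `dsem_data` list: `trials` (person_id, trial, logrt),
#'   `covariates` (person_id, age, fa), `truth` (full person table).
#' @export
simulate_dataset <- function(pop = default_population(), n_persons = 200L,
                             seed = 1L, cov_obs_fraction = NULL,
                             initial = "stationary") {
  persons <- draw_population(pop, n_persons, seed = seed)
  trials <- vector("list", n_persons)
  set.seed(seed + 104729L)
  for (i in seq_len(n_persons)) {
    eff <- person_effects(persons$mu[i], persons$phi[i], persons$bt[i],
                          persons$psi[i])
    trials[[i]] <- simulate_series(eff, pop$n_trials, seed = NULL,
                                   initial = initial,
                                   person_id = persons$person_id[i])
  }
  out <- structure(list(
    trials = do.call(rbind, trials),
    covariates = persons[, c("person_id", "age", "fa")],
    truth = persons
  ), class = "dsem_data")
  frac <- cov_obs_fraction %||% pop$cov_obs_fraction
  apply_missingness(out, frac, seed = seed + 224737L)
}

#' Write a synthetic dataset to CSV files
#'
#' Writes `trials.csv` (person_id, trial, rt_s, logrt), `covariates.csv`
#' (person_id, age, fa) and, when present, `truth.csv` with the generating
#' person effects. Missing values are written as empty fields.
#'
#' @param dataset a `dsem_data`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "dsem_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- dataset$trials
  tr$rt_s <- exp(tr$logrt)
  paths <- c(trials = file.path(dir, "trials.csv"),
             covariates = file.path(dir, "covariates.csv"))
  write.csv(tr[, c("person_id", "trial", "rt_s", "logrt")],
            paths[["trials"]], row.names = FALSE, na = "")
  write.csv(dataset$covariates, paths[["covariates"]], row.names = FALSE,
            na = "")
  if (!is.null(dataset$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    write.csv(dataset$truth, paths[["truth"]], row.names = FALSE, na = "")
  }
  invisible(paths)
}
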