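#' MCMC configuration
#'
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burn burn-in per chain; defaults to half of `n_iter` (PSR and all
#'   summaries use the post-burn-in half).
#' @param n_chains number of chains (>= 2 required for PSR).
#' @param seed integer seed governing initialization and sampling.
#' @param thin thinning interval for stored draws.
#' @param psr_threshold convergence bound on the potential scale reduction
#'   (default 1.10).
#' @param bias_threshold relative-bias bound for the robustness protocol
#'   (default 0.05).
#' @param max_doublings maximum iteration doublings in the robustness
#'   protocol (default 3).
#' @return an `mcmc_config` object.
#' @export
mcmc_config <- function(n_iter = 2000L, n_burn = NULL, n_chains = 2L,
                        seed = 1L, thin = 1L, psr_threshold = 1.10,
                        bias_threshold = 0.05, max_doublings = 3L) {
  n_burn <- as.integer(n_burn %||% (n_iter %/% 2L))
  if (n_iter <= n_burn) stop("n_iter must exceed n_burn")
  if (n_chains < 1) stop("need at least one chain")
  structure(list(n_iter = as.integer(n_iter), n_burn = n_burn,
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 thin = as.integer(thin), psr_threshold = psr_threshold,
                 bias_threshold = bias_threshold,
                 max_doublings = as.integer(max_doublings)),
            class = "mcmc_config")
}

#' Prior configuration
#'
#' Fixed-effect coefficients (all gamma and omega) get independent normal
#' priors, by default diffuse N(0, 10^2). The random-effect covariance tau
#' uses a flat (uniform over positive-definite matrices) prior with a
#' conjugate inverse-Wishart conditional — the convention of the DSEM
#' software this model class is associated with; scale-free alternatives of
#' the |tau|^-(d+1)/2 family place a density spike at singular tau that can
#' trap chains in a spurious zero-variance mode for weakly identified
#' components. The exogenous covariate distribution uses the Jeffreys
#' normal-inverse-Wishart form.
#'
#' @param gamma_mean prior mean, scalar or 4 x p matrix (rows mu, phi, bt,
#'   lpsi; columns intercept then covariates).
#' @param gamma_sd prior SD, scalar or 4 x p matrix.
#' @return a `dsem_prior` object.
#' @export
dsem_prior <- function(gamma_mean = 0, gamma_sd = 10) {
  structure(list(gamma_mean = gamma_mean, gamma_sd = gamma_sd),
            class = "dsem_prior")
}

# Expand one person's trials to a consecutive grid; absent rows become NA.
expand_series <- function(trial, logrt) {
  o <- order(trial)
  trial <- trial[o]; logrt <- logrt[o]
  if (anyDuplicated(trial)) stop("duplicate trial index within person")
  grid <- seq.int(trial[1], trial[length(trial)])
  y <- rep(NA_real_, length(grid))
  y[match(trial, grid)] <- logrt
  list(trial = as.numeric(grid), y = y)
}

prepare_fit_data <- function(dataset, spec) {
  trials <- if (inherits(dataset, "dsem_data")) dataset$trials else dataset
  stopifnot(all(c("person_id", "trial", "logrt") %in% names(trials)))
  ids <- unique(trials$person_id)
  ylist <- list(); trlist <- list(); keep <- logical(length(ids))
  for (k in seq_along(ids)) {
    sub <- trials[trials$person_id == ids[k], ]
    es <- expand_series(sub$trial, sub$logrt)
    nobs <- sum(is.finite(es$y))
    keep[k] <- nobs >= 2
    if (keep[k]) {
      obs <- es$y[is.finite(es$y)]
      if (stats::sd(obs) == 0 && nobs > 2)
        stop("degenerate all-constant series for person ", ids[k])
    }
    ylist[[k]] <- es$y; trlist[[k]] <- es$trial
  }
  if (!any(keep)) {
    return(list(ids = ids, y = ylist, trial = trlist, usable = keep,
                empty = TRUE))
  }
  if (sum(keep) < length(ids))
    warning(sum(!keep), " person(s) dropped: fewer than 2 non-missing trials")
  list(ids = ids[keep], y = ylist[keep], trial = trlist[keep],
       usable = keep, empty = FALSE)
}

# covariate design on the centered scale plus bookkeeping
prepare_covariates <- function(dataset, spec, ids) {
  use <- spec$include_covariates
  if (!any(use)) {
    return(list(X = matrix(1, length(ids), 1), x_mis = matrix(0L, length(ids), 0),
                cov_names = character(0), xbar = numeric(0)))
  }
  cv <- dataset$covariates
  stopifnot(!is.null(cv), "person_id" %in% names(cv))
  cn <- c("fa", "age")[use]
  missing_cols <- setdiff(cn, names(cv))
  if (length(missing_cols))
    stop("covariate column(s) not found: ", paste(missing_cols, collapse = ", "))
  m <- cv[match(ids, cv$person_id), cn, drop = FALSE]
  Xr <- as.matrix(m)
  if (all(!is.finite(Xr))) stop("covariate block enabled but no person has observed covariates")
  xbar <- colMeans(Xr, na.rm = TRUE)
  Xc <- sweep(Xr, 2, xbar)
  x_mis <- matrix(as.integer(!is.finite(Xc)), nrow(Xc), ncol(Xc))
  Xc[!is.finite(Xc)] <- 0
  list(X = cbind(1, Xc), x_mis = x_mis, cov_names = cn, xbar = xbar)
}

# per-person ridge least squares used for initialization
init_person_effects <- function(y, tr) {
  T <- length(y)
  M <- matrix(0, 3, 3); q <- numeric(3); s <- 0; ne <- 0
  for (t in 2:T) {
    if (!is.finite(y[t]) || !is.finite(y[t - 1])) next
    z <- c(1, y[t - 1], tr[t])
    M <- M + tcrossprod(z); q <- q + z * y[t]; s <- s + y[t]^2; ne <- ne + 1
  }
  b <- tryCatch(solve(M + diag(1e-4, 3), q), error = function(e) c(mean(y, na.rm = TRUE), 0, 0))
  if (abs(b[2]) > 0.95) b[2] <- sign(b[2]) * 0.5
  ssr <- max(s - 2 * sum(b * q) + drop(t(b) %*% M %*% b), 0)
  v <- log(max(ssr / max(ne - 3, 1), 1e-4))
  c(b, v)
}

param_names_for <- function(spec, cov_names) {
  suf <- c(intercept = "0", fa = "1", age = "2")
  cols <- c("intercept", cov_names)
  g <- character(0)
  for (j in 1:3) g <- c(g, paste0("gamma", j - 1, suf[cols]))
  g <- c(g, paste0("omega", suf[cols]))
  comps <- .comp_names[spec$include_random]
  tn <- character(0)
  if (length(comps)) {
    lab <- sub("lpsi", "psi", comps)
    for (a in seq_along(comps)) for (b in a:length(comps))
      tn <- c(tn, if (a == b) paste0("tau_", lab[a]) else paste0("tau_", lab[a], "_", lab[b]))
  }
  en <- character(0)
  if (length(cov_names)) {
    en <- paste0("exo_mean_", cov_names)
    for (a in seq_along(cov_names)) for (b in a:length(cov_names))
      en <- c(en, if (a == b) paste0("exo_var_", cov_names[a])
              else paste0("exo_cov_", cov_names[a], "_", cov_names[b]))
  }
  list(gamma = g, tau = tn, exo = en, all = c(g, tn, en))
}

#' Fit the dynamic location-scale model by MCMC
#'
#' Draws from the joint posterior of the two-level model: within persons an
#' AR(1)-plus-trend regression of log-RT with person-specific residual
#' variance; between persons a multivariate regression of the four
#' components (mu, phi, bt, log psi) on the enabled covariates with residual
#' covariance tau. Covariates are modeled jointly as multivariate normal so
#' persons with missing covariates contribute through their trial data
#' instead of being dropped; missing trial outcomes are imputed as latent
#' draws. Estimation uses a centered Gibbs sampler with adaptive
#' random-walk Metropolis steps for the log-variance parameters; all
#' conjugate blocks are exact. Covariates are centered internally and all
#' reported coefficients are returned on the raw scale.
#'
#' The sampler implements the raw-lag parameterization (regression on the
#' previous outcome as observed); `lag_centering = "latent_centered"` is
#' available in [conditional_loglik()] for likelihood evaluation but not
#' for fitting. Covariate blocks require all four random effects active.
#'
#' @param dataset a `dsem_data` (or a plain trials data frame for
#'   unconditional models).
#' @param spec a [model_spec()].
#' @param config an [mcmc_config()].
#' @param prior a [dsem_prior()].
#' @return a `dsem_fit` object with elements `draws` (array
#'   iterations x chains x parameters, post burn-in), `eta` (array
#'   iterations x chains x persons x 4 of person effects), `loglik`,
#'   `accept`, plus the spec/config/prior and prepared data.
#' @export
dsem_fit <- function(dataset, spec = model_spec(), config = mcmc_config(),
                     prior = dsem_prior()) {
  if (spec$lag_centering != "raw_lag")
    stop("the sampler supports lag_centering = 'raw_lag' only; ",
         "latent centering is available in conditional_loglik()")
  pd <- prepare_fit_data(dataset, spec)
  if (pd$empty) return(prior_only_fit(dataset, spec, config, prior, pd))
  n <- length(pd$ids)
  if (n < 2) stop("need >= 2 persons with >= 2 non-missing trials")
  if (any(spec$include_covariates) && !all(spec$include_random))
    stop("covariate blocks require all four random effects active")
  cv <- prepare_covariates(if (inherits(dataset, "dsem_data")) dataset else
    list(covariates = NULL), spec, pd$ids)
  p <- ncol(cv$X); ncov <- p - 1L
  da <- sum(spec$include_random)
  if (da > 0 && n < 2 * da + 2)
    stop("too few persons (", n, ") for ", da, " random effects")
  maxT <- max(vapply(pd$y, function(y) sum(is.finite(y)), 0))
  if (maxT < 4 && da > 0)
    warning("fewer than 4 trials per person: random effects weakly identified")

  pm <- matrix(prior$gamma_mean, 4, p)
  pp <- matrix(1 / matrix(prior$gamma_sd, 4, p)^2, 4, p)

  eta_base <- t(vapply(seq_len(n),
                       function(i) init_person_effects(pd$y[[i]], pd$trial[[i]]),
                       numeric(4)))
  nm <- param_names_for(spec, cv$cov_names)
  kept <- (config$n_iter - config$n_burn) %/% config$thin
  draws <- array(NA_real_, c(kept, config$n_chains, length(nm$all)),
                 dimnames = list(NULL, NULL, nm$all))
  eta_arr <- array(NA_real_, c(kept, config$n_chains, n, 4))
  ll <- matrix(NA_real_, kept, config$n_chains)
  accept <- matrix(NA_real_, config$n_chains, 2,
                   dimnames = list(NULL, c("v", "w")))

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  sdcol <- pmax(apply(eta_base, 2, stats::sd), c(0.02, 0.02, 5e-4, 0.05))

  comps_a <- which(spec$include_random)
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    eta0 <- eta_base + matrix(rnorm(n * 4), n, 4) %*% diag(0.5 * sdcol)
    G0 <- t(qr.solve(cv$X, eta0))
    res <- eta0 - cv$X %*% t(G0)
    tau0 <- stats::cov(res) + diag(0.1 * pmax(diag(stats::cov(res)), 1e-6))
    nu0 <- if (ncov > 0) rep(0, ncov) else numeric(0)
    Sig0 <- if (ncov > 0) {
      Xc <- cv$X[, -1, drop = FALSE]
      obs <- rowSums(cv$x_mis) == 0
      s <- stats::cov(Xc[obs, , drop = FALSE])
      s + diag(1e-8 + 0.01 * diag(s), ncov)
    } else matrix(0, 1, 1)
    out <- dsem_mcmc_chain(pd$y, pd$trial, cv$X, cv$x_mis,
                           spec$include_random,
                           config$n_iter, config$n_burn, config$thin,
                           pm, pp, G0, tau0, eta0,
                           if (ncov > 0) nu0 else numeric(1), Sig0)
    draws[, ch, ] <- assemble_draws(out, spec, cv, nm, kept)
    for (j in 1:4) eta_arr[, ch, , j] <- t(out$eta[, j, ])
    ll[, ch] <- out$loglik
    accept[ch, ] <- c(out$accept_v, out$accept_w)
  }

  structure(list(draws = draws, eta = eta_arr, loglik = ll, accept = accept,
                 spec = spec, config = config, prior = prior,
                 data = list(ids = pd$ids, y = pd$y, trial = pd$trial,
                             X = cv$X, x_mis = cv$x_mis,
                             cov_names = cv$cov_names, xbar = cv$xbar),
                 param_names = nm),
            class = "dsem_fit")
}

# flatten one chain's cubes into the named draw matrix, back-transforming
# intercepts and exogenous means to the raw covariate scale
assemble_draws <- function(out, spec, cv, nm, kept) {
  p <- ncol(cv$X); ncov <- p - 1L
  res <- matrix(NA_real_, kept, length(nm$all),
                dimnames = list(NULL, nm$all))
  suf <- c(intercept = "0", fa = "1", age = "2")
  cols <- c("intercept", cv$cov_names)
  for (j in 1:4) {
    pref <- if (j < 4) paste0("gamma", j - 1) else "omega"
    Gj <- t(out$G[j, , , drop = TRUE])          # kept x p (p>1) or vector
    if (p == 1) Gj <- matrix(out$G[j, 1, ], ncol = 1)
    icpt <- Gj[, 1]
    if (ncov > 0) icpt <- icpt - Gj[, -1, drop = FALSE] %*% cv$xbar
    res[, paste0(pref, "0")] <- icpt
    if (ncov > 0)
      for (k in seq_len(ncov))
        res[, paste0(pref, suf[cv$cov_names[k]])] <- Gj[, k + 1]
  }
  comps <- which(spec$include_random)
  if (length(comps)) {
    ti <- 0
    for (a in seq_along(comps)) for (b in a:length(comps)) {
      ti <- ti + 1
      res[, nm$tau[ti]] <- out$tau[comps[a], comps[b], ]
    }
  }
  if (ncov > 0) {
    for (k in seq_len(ncov))
      res[, paste0("exo_mean_", cv$cov_names[k])] <-
        out$exo_mean[, k] + cv$xbar[k]
    ti <- 0
    en <- nm$exo[-(seq_len(ncov))]
    for (a in seq_len(ncov)) for (b in a:ncov) {
      ti <- ti + 1
      res[, en[ti]] <- out$exo_cov[a, b, ]
    }
  }
  res
}

# Degenerate mode used by the prior-predictive check: a dataset whose series
# are all empty yields prior draws for the fixed effects (fixed-effects spec
# only; tau has no proper prior without data).
prior_only_fit <- function(dataset, spec, config, prior, pd) {
  if (any(spec$include_random))
    stop("no usable series: prior-only sampling requires a fixed-effects spec")
  if (any(spec$include_covariates))
    stop("no usable series: cannot fit covariate blocks")
  nm <- param_names_for(spec, character(0))
  kept <- (config$n_iter - config$n_burn) %/% config$thin
  pm <- matrix(prior$gamma_mean, 4, 1)
  ps <- matrix(prior$gamma_sd, 4, 1)
  draws <- array(NA_real_, c(kept, config$n_chains, length(nm$all)),
                 dimnames = list(NULL, NULL, nm$all))
  set.seed(config$seed)
  for (ch in seq_len(config$n_chains))
    for (j in 1:4)
      draws[, ch, j] <- rnorm(kept, pm[j, 1], ps[j, 1])
  structure(list(draws = draws, eta = NULL, loglik = NULL, accept = NULL,
                 spec = spec, config = config, prior = prior,
                 data = list(ids = pd$ids, y = pd$y, trial = pd$trial,
                             X = NULL, cov_names = character(0)),
                 param_names = nm, prior_only = TRUE),
            class = "dsem_fit")
}

#' @export
print.dsem_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat("dsem_fit:", d[1], "kept draws x", d[2], "chains,",
      d[3], "parameters;", length(x$data$ids), "persons\n")
  re <- .comp_names[x$spec$include_random]
  cat("random effects:", if (length(re)) paste(re, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

# posterior means of the monitored parameters, named
monitored_estimates <- function(fit) {
  apply(fit$draws, 3, mean)
}

# draws collapsed over chains: matrix (iter*chains) x param
flat_draws <- function(fit) {
  d <- dim(fit$draws)
  m <- matrix(aperm(fit$draws, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(m) <- dimnames(fit$draws)[[3]]
  m
}
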