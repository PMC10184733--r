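#' Potential scale reduction (Gelman-Rubin) per parameter
#'
#' Compares between-chain and within-chain variance of the post-burn-in
#' draws. For chain length n and m chains with within-chain variance W
#' (mean of the per-chain sample variances) and between-chain variance B
#' (n times the variance of the chain means), the statistic is
#' `sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate that further
#' sampling would not materially narrow the posterior; the conventional
#' convergence rule used here is PSR < 1.10 for every monitored parameter.
#'
#' @param fit a `dsem_fit`, or a draws array (iterations x chains x
#'   parameters).
#' @param threshold convergence bound (defaults to the fit's configured
#'   1.10).
#' @return named vector of PSR values with attributes `converged` (logical)
#'   and `threshold`.
#' @export
psr <- function(fit, threshold = NULL) {
  draws <- if (inherits(fit, "dsem_fit")) fit$draws else fit
  threshold <- threshold %||%
    (if (inherits(fit, "dsem_fit")) fit$config$psr_threshold else 1.10)
  d <- dim(draws)
  if (is.na(d[2]) || d[2] < 2)
    stop("PSR requires >= 2 chains; refit with n_chains >= 2 ",
         "or split each chain in half before calling")
  n <- d[1]; m <- d[2]
  out <- vapply(seq_len(d[3]), function(j) {
    x <- draws[, , j, drop = FALSE]
    cm <- colMeans(x[, , 1])
    W <- mean(apply(x[, , 1], 2, stats::var))
    B_over_n <- stats::var(cm)
    if (W == 0) return(if (B_over_n == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
  names(out) <- dimnames(draws)[[3]]
  structure(out, converged = all(is.finite(out) & out < threshold),
            threshold = threshold)
}

#' Relative bias between two parameter solutions
#'
#' For each shared parameter, `|b - a| / |a|`; when the reference value `a`
#' is (numerically) zero the absolute difference is reported instead and
#' flagged. The summary attribute is the maximum over parameters, the
#' quantity the robustness protocol thresholds at 5%.
#'
#' @param solution_a named numeric vector of reference estimates.
#' @param solution_b named numeric vector, same names.
#' @param zero_tol reference magnitudes below this are treated as zero.
#' @return named vector of per-parameter proportions with attributes
#'   `max_bias` and `absolute_flag` (logical vector marking zero-reference
#'   parameters).
#' @export
relative_bias <- function(solution_a, solution_b, zero_tol = 1e-12) {
  if (!setequal(names(solution_a), names(solution_b)))
    stop("parameter names do not match between solutions")
  b <- solution_b[names(solution_a)]
  zero <- abs(solution_a) <= zero_tol
  out <- ifelse(zero, abs(b - solution_a), abs(b - solution_a) / abs(solution_a))
  structure(out, max_bias = max(out), absolute_flag = zero)
}

#' Iteration-doubling robustness protocol
#'
#' Implements the model-retention rule: fit with N and 2N iterations under
#' the same seed, then twice more with 2N iterations under fresh seeds;
#' compute the relative bias of each alternative solution against the 2N
#' same-seed reference; if the maximum bias across monitored parameters is
#' below the threshold for all three comparisons, retain the reference fit.
#' Monitored are the fixed effects, the omegas, the tau diagonal and the
#' tau correlations; a parameter whose reference estimate is statistically
#' indistinguishable from zero (within 2 posterior SDs) cannot anchor a
#' stability ratio and is flagged in the audit instead of entering the
#' maximum.
#' Otherwise double all iteration counts and repeat, up to `max_doublings`
#' escalations; exhausting them yields a non-convergence report rather than
#' an error.
#'
#' @param dataset,spec,prior passed to [dsem_fit()].
#' @param base_config an [mcmc_config()]; its `n_iter` is the starting N and
#'   its `bias_threshold`/`max_doublings` govern the protocol.
#' @return list with `retained` (logical), `fit` (the retained fit or the
#'   last reference), `stage` (1-based stage at which the protocol stopped),
#'   `audit` (one data frame per stage listing every fit and its maximum
#'   relative bias against the stage reference), and `psr` of the retained
#'   fit.
#' @export
convergence_protocol <- function(dataset, spec = model_spec(),
                                 base_config = mcmc_config(),
                                 prior = dsem_prior()) {
  audit <- list()
  ref_fit <- NULL
  for (stage in seq_len(base_config$max_doublings + 1L)) {
    N <- base_config$n_iter * 2L^(stage - 1L)
    cfg <- function(iters, seed) {
      c2 <- base_config
      c2$n_iter <- as.integer(iters); c2$n_burn <- as.integer(iters %/% 2L)
      c2$seed <- as.integer(seed)
      c2
    }
    s0 <- base_config$seed
    fits <- list(
      half  = dsem_fit(dataset, spec, cfg(N, s0), prior),
      ref   = dsem_fit(dataset, spec, cfg(2L * N, s0), prior),
      seed2 = dsem_fit(dataset, spec, cfg(2L * N, s0 + 1L), prior),
      seed3 = dsem_fit(dataset, spec, cfg(2L * N, s0 + 2L), prior))
    ref <- protocol_estimates(fits$ref)
    # a stability ratio needs a reference distinguishable from zero: skip
    # parameters whose reference estimate sits within 2 posterior SDs of 0
    # (they are flagged, not silently passed)
    det <- abs(ref$estimate) >= 2 * ref$sd_post
    if (!any(det)) stop("no determinate monitored parameters for the bias rule")
    mb <- vapply(fits[c("half", "seed2", "seed3")], function(f) {
      b <- relative_bias(ref$estimate, protocol_estimates(f)$estimate)
      max(b[det])
    }, numeric(1))
    audit[[stage]] <- data.frame(
      fit = c("half", "ref", "seed2", "seed3"),
      n_iter = c(N, 2L * N, 2L * N, 2L * N),
      seed = c(s0, s0, s0 + 1L, s0 + 2L),
      max_bias = c(mb["half"], NA, mb["seed2"], mb["seed3"]),
      n_indeterminate = sum(!det))
    ref_fit <- fits$ref
    if (all(mb < base_config$bias_threshold)) {
      return(list(retained = TRUE, fit = ref_fit, stage = stage,
                  audit = audit, psr = psr(ref_fit)))
    }
  }
  list(retained = FALSE, fit = ref_fit,
       stage = base_config$max_doublings + 1L, audit = audit,
       psr = psr(ref_fit))
}

# Monitored quantities for the robustness protocol: fixed effects, omegas,
# tau diagonal, and tau correlations (not raw covariances, whose relative
# bias is dominated by Monte-Carlo noise at small magnitudes). Returns the
# posterior mean and SD of each.
protocol_estimates <- function(fit) {
  m <- flat_draws(fit)
  keep <- grep("^(gamma[0-2][0-2]|omega[0-2]|tau_(mu|phi|bt|psi))$",
               colnames(m))
  m <- m[, keep, drop = FALSE]
  if (any(fit$spec$include_random) && sum(fit$spec$include_random) > 1) {
    rc <- random_effect_correlations(fit)$draws
    m <- cbind(m, rc)
  }
  list(estimate = colMeans(m), sd_post = apply(m, 2, stats::sd))
}

# per-person crossproducts over observed lag pairs (shared by dic/r2)
observed_crossprods <- function(fit) {
  lapply(seq_along(fit$data$y), function(i) {
    y <- fit$data$y[[i]]; tr <- fit$data$trial[[i]]
    M <- matrix(0, 3, 3); q <- numeric(3); s <- 0; ne <- 0
    for (t in 2:length(y)) {
      if (!is.finite(y[t]) || !is.finite(y[t - 1])) next
      z <- c(1, y[t - 1], tr[t])
      M <- M + tcrossprod(z); q <- q + z * y[t]; s <- s + y[t]^2; ne <- ne + 1
    }
    list(M = M, q = q, s = s, ne = ne)
  })
}

#' Deviance information criterion
#'
#' DIC conditional on the person-level effects: the deviance is
#' `-2 * sum_i log p(y_i | mu_i, phi_i, bt_i, psi_i)` over observed trials
#' t >= 2, evaluated per posterior draw (Dbar) and at the posterior mean of
#' the person effects (Dhat, with psi at the posterior mean of log psi);
#' `pD = Dbar - Dhat` and `DIC = Dbar + pD`. Lower is better. The
#' conditional (random-effect-level) focus matches how the fixed- versus
#' random-effects comparison is customarily reported for this model class.
#'
#' @param fit a `dsem_fit`.
#' @return list with elements `dic`, `pD`, `Dbar`, `Dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "dsem_fit"))
  if (isTRUE(fit$prior_only)) stop("DIC is undefined for a prior-only fit")
  cp <- observed_crossprods(fit)
  d <- dim(fit$eta)          # kept x chains x n x 4
  nk <- d[1] * d[2]; n <- d[3]
  ll <- numeric(nk)
  eta_hat <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    B <- matrix(fit$eta[, , i, 1:3], nk, 3)
    v <- as.vector(fit$eta[, , i, 4])
    M <- cp[[i]]$M; q <- cp[[i]]$q
    SSR <- cp[[i]]$s - 2 * (B %*% q) + rowSums((B %*% M) * B)
    SSR <- pmax(SSR, 0)
    ll <- ll - 0.5 * cp[[i]]$ne * (log(2 * pi) + v) - 0.5 * SSR * exp(-v)
    eta_hat[i, ] <- c(colMeans(B), mean(v))
  }
  Dbar <- mean(-2 * ll)
  llhat <- 0
  for (i in seq_len(n)) {
    b <- eta_hat[i, 1:3]; v <- eta_hat[i, 4]
    SSR <- max(cp[[i]]$s - 2 * sum(b * cp[[i]]$q) +
                 drop(t(b) %*% cp[[i]]$M %*% b), 0)
    llhat <- llhat - 0.5 * cp[[i]]$ne * (log(2 * pi) + v) -
      0.5 * SSR * exp(-v)
  }
  Dhat <- -2 * llhat
  pD <- Dbar - Dhat
  list(dic = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Difference in DIC between two fits
#'
#' `dic(fit_b)$dic - dic(fit_a)$dic`: negative values favor `fit_b`.
#'
#' @param fit_a,fit_b fitted models of the same data.
#' @return scalar DIC difference.
#' @export
delta_dic <- function(fit_a, fit_b) {
  if (!identical(length(fit_a$data$ids), length(fit_b$data$ids)))
    stop("fits are not of the same dataset")
  dic(fit_b)$dic - dic(fit_a)$dic
}
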