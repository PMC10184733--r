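#' Posterior parameter table
#'
#' Posterior mean (the reported estimate), posterior SD, and equal-tailed
#' percentile credible interval per parameter.
#'
#' @param fit a `dsem_fit`, or a draws matrix (draws x parameters).
#' @param level interval probability (default 0.95).
#' @return data frame with columns `parameter`, `estimate`, `sd_post`,
#'   `lower`, `upper`.
#' @export
summarize_draws <- function(fit, level = 0.95) {
  m <- if (inherits(fit, "dsem_fit")) flat_draws(fit) else as.matrix(fit)
  if (nrow(m) == 0) stop("no draws to summarize")
  a <- (1 - level) / 2
  data.frame(
    parameter = colnames(m) %||% paste0("par", seq_len(ncol(m))),
    estimate = colMeans(m),
    sd_post = apply(m, 2, stats::sd),
    lower = apply(m, 2, stats::quantile, probs = a, names = FALSE),
    upper = apply(m, 2, stats::quantile, probs = 1 - a, names = FALSE),
    row.names = NULL)
}

#' Average within-person standardized dynamic effects
#'
#' Standardizes the autoregressive and trend coefficients within each
#' person's own series — coefficient times SD(predictor)/SD(outcome), with
#' the SDs computed over that person's observed trials (the lagged outcome
#' and the trial index are the predictors) — then averages over persons.
#' The whole map is applied per posterior draw, so the result is a
#' posterior distribution of the average standardized effect.
#'
#' @param fit a `dsem_fit` with person-level draws.
#' @return list with `draws` (matrix draws x 2, columns `phi_std`,
#'   `bt_std`) and `summary` (the [summarize_draws()] table).
#' @export
standardized_within_effects <- function(fit) {
  stopifnot(inherits(fit, "dsem_fit"))
  if (is.null(fit$eta)) stop("fit carries no person-level draws")
  n <- dim(fit$eta)[3]
  ratio <- matrix(NA_real_, n, 2)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    y <- fit$data$y[[i]]; tr <- fit$data$trial[[i]]
    ok <- which(is.finite(y[-1]) & is.finite(y[-length(y)]))
    yo <- y[ok + 1]; ylag <- y[ok]; to <- tr[ok + 1]
    sy <- stats::sd(yo)
    if (!is.finite(sy) || sy == 0) { keep[i] <- FALSE; next }
    ratio[i, ] <- c(stats::sd(ylag) / sy, stats::sd(to) / sy)
  }
  if (!all(keep))
    warning(sum(!keep), " person(s) with zero outcome variance excluded")
  d <- dim(fit$eta); nk <- d[1] * d[2]
  phi_d <- matrix(fit$eta[, , keep, 2], nk, sum(keep))
  bt_d <- matrix(fit$eta[, , keep, 3], nk, sum(keep))
  draws <- cbind(
    phi_std = rowMeans(sweep(phi_d, 2, ratio[keep, 1], `*`)),
    bt_std = rowMeans(sweep(bt_d, 2, ratio[keep, 2], `*`)))
  list(draws = draws, summary = summarize_draws(draws))
}

#' Covariance to correlation
#'
#' `r_jk = tau_jk / sqrt(tau_jj * tau_kk)`.
#'
#' @param tau covariance matrix with strictly positive diagonal.
#' @return correlation matrix with unit diagonal.
#' @export
cov_to_corr <- function(tau) {
  tau <- as.matrix(tau)
  if (any(diag(tau) <= 0)) stop("zero or negative diagonal element in tau")
  s <- sqrt(diag(tau))
  tau / tcrossprod(s)
}

# tau draws of a fit as draws x d x d array (active components only)
tau_draw_array <- function(fit) {
  comps <- which(fit$spec$include_random)
  d <- length(comps)
  if (d == 0) stop("fit has no random effects")
  lab <- sub("lpsi", "psi", .comp_names[comps])
  m <- flat_draws(fit)
  arr <- array(NA_real_, c(nrow(m), d, d), dimnames = list(NULL, lab, lab))
  for (a in seq_len(d)) for (b in a:d) {
    nmab <- if (a == b) paste0("tau_", lab[a]) else paste0("tau_", lab[a], "_", lab[b])
    arr[, a, b] <- arr[, b, a] <- m[, nmab]
  }
  arr
}

#' Posterior random-effect correlations
#'
#' Converts every tau draw to a correlation matrix and summarizes the
#' posterior of each pairwise correlation.
#'
#' @param fit a `dsem_fit` with random effects.
#' @return list with `draws` (draws x pairs) and `summary`.
#' @export
random_effect_correlations <- function(fit) {
  arr <- tau_draw_array(fit)
  d <- dim(arr)[2]; lab <- dimnames(arr)[[2]]
  pairs <- which(upper.tri(diag(d)), arr.ind = TRUE)
  draws <- sapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    arr[, a, b] / sqrt(arr[, a, a] * arr[, b, b])
  })
  colnames(draws) <- paste0("r_", lab[pairs[, 1]], "_", lab[pairs[, 2]])
  list(draws = draws, summary = summarize_draws(draws))
}

#' Between-person variance explained by covariates
#'
#' For each random effect, `R^2 = 1 - tau_cond / tau_uncond` comparing the
#' residual variance from a covariate-conditional fit against the total
#' variance from an unconditional fit of the same data, computed per
#' draw-pair (draws are paired by index across the two independent chains'
#' concatenation; the pairing is arbitrary but propagates posterior spread
#' into the R^2 interval) and clipped below at 0. Draw pairs where the
#' conditional variance exceeds the unconditional are counted in
#' `negative_fraction`.
#'
#' @param fit_uncond,fit_cond unconditional and conditional fits of the
#'   same persons with the same random effects.
#' @return list with `draws`, `summary`, and `negative_fraction` per
#'   effect.
#' @export
r2_between <- function(fit_uncond, fit_cond) {
  tu <- tau_draw_array(fit_uncond)
  tc <- tau_draw_array(fit_cond)
  if (!identical(dimnames(tu)[[2]], dimnames(tc)[[2]]))
    stop("fits have different random-effect sets")
  nd <- min(dim(tu)[1], dim(tc)[1])
  lab <- dimnames(tu)[[2]]
  raw <- sapply(seq_along(lab), function(j)
    1 - tc[seq_len(nd), j, j] / tu[seq_len(nd), j, j])
  colnames(raw) <- paste0("r2_", lab)
  neg <- colMeans(raw < 0)
  draws <- pmax(raw, 0)
  list(draws = draws, summary = summarize_draws(draws),
       negative_fraction = neg)
}

#' Within-person variance explained by the dynamic predictors
#'
#' Per person, one minus the residual variance over the sample variance of
#' the outcome (the share of trial-to-trial variance captured by the lag
#' and trend), averaged over persons per posterior draw.
#'
#' @param fit a `dsem_fit` with person-level draws.
#' @return list with `draws` (vector) and `summary`.
#' @export
r2_within <- function(fit) {
  stopifnot(inherits(fit, "dsem_fit"))
  n <- dim(fit$eta)[3]
  d <- dim(fit$eta); nk <- d[1] * d[2]
  vy <- vapply(fit$data$y, function(y) stats::var(y[is.finite(y)]), numeric(1))
  keep <- is.finite(vy) & vy > 0
  v <- matrix(fit$eta[, , keep, 4], nk, sum(keep))
  r2 <- rowMeans(pmax(1 - sweep(exp(v), 2, vy[keep], `/`), 0))
  draws <- cbind(r2_within = r2)
  list(draws = draws, summary = summarize_draws(draws))
}

#' Standardized between-person covariate effects
#'
#' Per draw, each covariate coefficient is scaled by SD(covariate) /
#' SD(random effect), the conventional standardization for a between-level
#' regression: the covariate SD comes from the jointly estimated exogenous
#' model and the effect SD from the model-implied total variance
#' (covariate-explained plus residual tau).
#'
#' @param fit a conditional `dsem_fit` (covariate blocks enabled).
#' @return list with `draws` (draws x coefficients, names like
#'   `std_gamma01`) and `summary`.
#' @export
standardized_between_effects <- function(fit) {
  cn <- fit$data$cov_names
  if (length(cn) == 0) stop("fit has no covariate blocks")
  m <- flat_draws(fit)
  suf <- c(fa = "1", age = "2")
  lab <- sub("lpsi", "psi", .comp_names)
  # covariate covariance draws
  ncov <- length(cn)
  Sg <- array(NA_real_, c(nrow(m), ncov, ncov))
  for (a in seq_len(ncov)) for (b in a:ncov) {
    nmab <- if (a == b) paste0("exo_var_", cn[a])
            else paste0("exo_cov_", cn[a], "_", cn[b])
    Sg[, a, b] <- Sg[, b, a] <- m[, nmab]
  }
  out <- NULL
  for (j in 1:4) {
    pref <- if (j < 4) paste0("gamma", j - 1) else "omega"
    gnames <- paste0(pref, suf[cn])
    g <- m[, gnames, drop = FALSE]
    tau_j <- m[, paste0("tau_", lab[j])]
    expl <- vapply(seq_len(nrow(m)), function(r)
      drop(t(g[r, ]) %*% Sg[r, , ] %*% g[r, ]), numeric(1))
    sd_eff <- sqrt(expl + tau_j)
    for (k in seq_len(ncov)) {
      std <- g[, k] * sqrt(Sg[, k, k]) / sd_eff
      out <- cbind(out, std)
      colnames(out)[ncol(out)] <- paste0("std_", gnames[k])
    }
  }
  list(draws = out, summary = summarize_draws(out))
}

#' Person-level factor scores
#'
#' Posterior mean of each person's four components (mu, phi, bt, log psi).
#' These are shrinkage estimates: their between-person variance is smaller
#' than the posterior mean of tau because each person's estimate is pulled
#' toward the covariate-implied population value in proportion to the
#' information in their series.
#'
#' @param fit a `dsem_fit` with at least one random effect.
#' @return data frame `person_id`, `mu`, `phi`, `bt`, `lpsi`.
#' @export
factor_scores <- function(fit) {
  stopifnot(inherits(fit, "dsem_fit"))
  if (!any(fit$spec$include_random))
    stop("fixed-effects-only fit: no person-level scores exist")
  d <- dim(fit$eta)
  sc <- sapply(1:4, function(j)
    colMeans(matrix(fit$eta[, , , j], d[1] * d[2], d[3])))
  colnames(sc) <- .comp_names
  data.frame(person_id = fit$data$ids, sc)
}

#' Two-sided p-value from a posterior estimate and SD
#'
#' `p = 2 * (1 - Phi(|estimate / posterior_sd|))`: the normal-approximation
#' tail probability used when the posterior summary (not the full draws)
#' is the available precision.
#'
#' @param estimate numeric vector of estimates.
#' @param posterior_sd matching positive posterior SDs.
#' @return vector of two-sided p-values.
#' @export
p_from_posterior <- function(estimate, posterior_sd) {
  if (any(posterior_sd <= 0)) stop("posterior_sd must be > 0")
  2 * stats::pnorm(-abs(estimate / posterior_sd))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, capped at 1, with the input
#' order restored.
#'
#' @param pvals p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
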