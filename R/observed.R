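#' Observed intraindividual variability metrics
#'
#' The conventional per-person summaries computed directly from the
#' log-scale trial series: the intraindividual SD (iSD, sample SD with
#' denominator n-1 over non-missing trials) and the coefficient of
#' variation (iCV = iSD divided by the person's mean log-RT). The iCV is
#' undefined when the mean log-RT is zero and is flagged rather than
#' computed; note that with log-second RTs below 1 s the mean is negative
#' and the iCV inherits its sign.
#'
#' @param x a `trial_series` data frame, a full trials table
#'   (`person_id`, `trial`, `logrt`), or a `dsem_data`.
#' @return data frame `person_id`, `n_trials`, `mean_logrt`, `isd`, `icv`,
#'   `icv_defined`.
#' @export
observed_variability <- function(x) {
  trials <- if (inherits(x, "dsem_data")) x$trials else x
  stopifnot(all(c("person_id", "logrt") %in% names(trials)))
  ids <- unique(trials$person_id)
  out <- lapply(ids, function(id) {
    y <- trials$logrt[trials$person_id == id]
    y <- y[is.finite(y)]
    if (length(y) < 2) stop("person ", id, ": need >= 2 non-missing trials")
    m <- mean(y); isd <- stats::sd(y)
    defined <- m != 0
    data.frame(person_id = id, n_trials = length(y), mean_logrt = m,
               isd = isd, icv = if (defined) isd / m else NA_real_,
               icv_defined = defined)
  })
  do.call(rbind, out)
}

#' Regress an observed variability metric on the four factor scores
#'
#' Ordinary least squares of the per-person observed metric on the four
#' model-based factor scores (mu, phi, bt, lpsi), reported as standardized
#' coefficients (all variables scaled to unit variance) with standard
#' errors, p-values, and the regression R-squared. This is the two-step
#' contamination analysis: a metric that purely measured residual
#' variability would load only on the lpsi score.
#'
#' @param scores data frame from [factor_scores()] (columns `person_id`,
#'   `mu`, `phi`, `bt`, `lpsi`).
#' @param metric numeric vector of per-person observed values aligned with
#'   `scores`, or a data frame with `person_id` and a single metric column.
#' @param metric_name label used in the output.
#' @return list with `coefficients` (data frame: term, beta, se, p),
#'   `r_squared`, and the underlying `lm` fit.
#' @export
regress_observed_on_scores <- function(scores, metric,
                                       metric_name = "metric") {
  sc <- scores[, c("mu", "phi", "bt", "lpsi")]
  if (is.data.frame(metric)) {
    mcol <- setdiff(names(metric), "person_id")[1]
    metric_name <- mcol
    metric <- metric[[mcol]][match(scores$person_id, metric$person_id)]
  }
  stopifnot(length(metric) == nrow(sc))
  if (nrow(sc) < ncol(sc) + 5)
    stop("need at least 5 more persons than predictors")
  Xs <- scale(as.matrix(sc))
  if (kappa(Xs, exact = TRUE) > 1e8)
    stop("factor scores are collinear (condition number > 1e8)")
  ys <- drop(scale(metric))
  df <- data.frame(y = ys, Xs)
  fit <- stats::lm(y ~ mu + phi + bt + lpsi, data = df)
  cf <- summary(fit)$coefficients[-1, , drop = FALSE]
  list(coefficients = data.frame(term = rownames(cf),
                                 beta = cf[, 1], se = cf[, 2],
                                 p = cf[, 4], row.names = NULL),
       r_squared = summary(fit)$r.squared,
       metric = metric_name,
       lm = fit)
}
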