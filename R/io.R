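#' Read a trials CSV
#'
#' Expects columns `person_id`, `trial`, and `rt_s` (reaction time in
#' seconds) or `logrt`. When `rt_s` is given the natural log is taken;
#' non-positive RTs are dropped with a logged count. Trials are sorted
#' within person and duplicate (person, trial) pairs are an error.
#'
#' @param path CSV path.
#' @return trials data frame (`person_id`, `trial`, `logrt`) with attribute
#'   `n_dropped_nonpositive`.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path)
  need <- c("person_id", "trial")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!any(c("rt_s", "logrt") %in% names(df)))
    stop("missing required column(s): rt_s or logrt")
  dropped <- 0L
  if (!"logrt" %in% names(df)) {
    bad <- is.finite(df$rt_s) & df$rt_s <= 0
    dropped <- sum(bad)
    if (dropped > 0) {
      warning(dropped, " trial(s) with non-positive RT dropped")
      df <- df[!bad, ]
    }
    df$logrt <- log(df$rt_s)
  }
  if (anyDuplicated(df[, c("person_id", "trial")]))
    stop("duplicate (person_id, trial) rows")
  df <- df[order(df$person_id, df$trial), c("person_id", "trial", "logrt")]
  rownames(df) <- NULL
  attr(df, "n_dropped_nonpositive") <- dropped
  df
}

#' Read a person-level covariate CSV
#'
#' Expects `person_id` plus covariate columns (e.g. `age` and one or more
#' FA tract columns). Empty fields become `NA`.
#'
#' @param path CSV path.
#' @return covariates data frame.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path)
  if (!"person_id" %in% names(df)) stop("missing required column: person_id")
  if (anyDuplicated(df$person_id)) stop("duplicate person_id rows")
  df
}

#' Screen FA outliers by tract-wise z-score
#'
#' Per tract, values more than `threshold_sd` SDs from the tract mean
#' (computed over observed values) are set to missing. Used as the
#' sensitivity screen for implausible scalar FA values.
#'
#' @param covariates covariate data frame.
#' @param threshold_sd positive threshold in SD units (default 4).
#' @param tracts columns to screen; defaults to every column except
#'   `person_id` and `age`.
#' @return list with `covariates` (screened) and `report` (per tract:
#'   `n_total` observed, `n_removed`, `fraction`).
#' @export
screen_fa_outliers <- function(covariates, threshold_sd = 4,
                               tracts = NULL) {
  if (threshold_sd <= 0) stop("threshold_sd must be > 0")
  tracts <- tracts %||% setdiff(names(covariates), c("person_id", "age"))
  rep_rows <- lapply(tracts, function(tr) {
    x <- covariates[[tr]]
    obs <- is.finite(x)
    if (sum(obs) < 2) stop("tract ", tr, ": need >= 2 observed values")
    z <- (x - mean(x[obs])) / stats::sd(x[obs])
    out <- obs & abs(z) > threshold_sd
    covariates[[tr]][out] <<- NA_real_
    data.frame(tract = tr, n_total = sum(obs), n_removed = sum(out),
               fraction = sum(out) / sum(obs))
  })
  list(covariates = covariates, report = do.call(rbind, rep_rows))
}

#' Pipeline run configuration
#'
#' @param trials_csv,covariates_csv input paths (either may be `NULL` when
#'   a `dataset` is passed to [run_pipeline()] directly).
#' @param output_dir directory for all artifacts.
#' @param tracts FA column names to model, one conditional model per tract.
#' @param spec base [model_spec()] (random-effect flags; covariate flags
#'   are set per stage).
#' @param config [mcmc_config()].
#' @param prior [dsem_prior()].
#' @param fa_screen logical: apply the FA outlier screen.
#' @param fa_threshold_sd screen threshold (SD units, default 4).
#' @param verbose logical.
#' @return a `run_config` object.
#' @export
run_config <- function(trials_csv = NULL, covariates_csv = NULL,
                       output_dir = "dsem_out", tracts = "fa",
                       spec = model_spec(), config = mcmc_config(),
                       prior = dsem_prior(), fa_screen = TRUE,
                       fa_threshold_sd = 4, verbose = TRUE) {
  if (fa_threshold_sd <= 0) stop("fa_threshold_sd must be > 0")
  structure(list(trials_csv = trials_csv, covariates_csv = covariates_csv,
                 output_dir = output_dir, tracts = tracts, spec = spec,
                 config = config, prior = prior, fa_screen = fa_screen,
                 fa_threshold_sd = fa_threshold_sd, verbose = verbose),
            class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(list(tracts = cfg$tracts, spec = cfg$spec,
               config = cfg$config, prior = cfg$prior,
               fa_screen = cfg$fa_screen,
               fa_threshold_sd = cfg$fa_threshold_sd), f, version = 2)
  unname(tools::md5sum(f))
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", stamp$hash, " seed=", stamp$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_stamped_csv <- function(path) utils::read.csv(path, comment.char = "#")

#' Run the full modeling workflow
#'
#' Executes the study workflow on one dataset: optional FA outlier screen,
#' an unconditional full-random-effects fit, then per tract a conditional
#' fit with the tract FA alone and one with FA plus age; within each
#' conditional model the covariate coefficients get posterior-SE p-values
#' with Benjamini-Hochberg adjustment (the FDR family is the set of
#' covariate tests within one model). Writes per-model parameter tables
#' (estimate, posterior SD, credible bounds), adjusted-p tables, a
#' cross-tract table of the FA effect on log residual variance, monitored
#' draws, and a JSON summary; every CSV is stamped with the config hash
#' and seed, and a manifest lists all artifacts.
#'
#' @param cfg a [run_config()].
#' @param dataset optional `dsem_data`; when `NULL` the CSV paths in `cfg`
#'   are read.
#' @return invisibly, a list with the fits, tables, and artifact paths.
#' @export
run_pipeline <- function(cfg, dataset = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (cfg$verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(hash = config_hash(cfg), seed = cfg$config$seed)

  if (is.null(dataset)) {
    trials <- stage("read_trials", read_trials(cfg$trials_csv))
    covs <- stage("read_covariates", read_covariates(cfg$covariates_csv))
    dataset <- structure(list(trials = trials, covariates = covs),
                         class = "dsem_data")
  }
  n_person <- length(unique(dataset$trials$person_id))
  n_obs_cov <- if (!is.null(dataset$covariates))
    sum(stats::complete.cases(dataset$covariates[, cfg$tracts[1], drop = FALSE]))
  else 0L
  say("persons: ", n_person, "; trial rows: ", nrow(dataset$trials),
      "; covariate-observed persons: ", n_obs_cov)

  screen_report <- NULL
  if (cfg$fa_screen && !is.null(dataset$covariates)) {
    scr <- stage("fa_screen",
                 screen_fa_outliers(dataset$covariates, cfg$fa_threshold_sd,
                                    tracts = cfg$tracts))
    dataset$covariates <- scr$covariates
    screen_report <- scr$report
    say("FA screen: ", sum(scr$report$n_removed), " value(s) removed")
  }

  paths <- character(0)
  add_csv <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    write_stamped_csv(df, p, stamp)
    paths[[name]] <<- p
    p
  }

  spec_u <- cfg$spec
  spec_u$include_covariates <- c(fa = FALSE, age = FALSE)
  say("fitting unconditional model")
  fit_u <- stage("unconditional_fit",
                 dsem_fit(dataset, spec_u, cfg$config, cfg$prior))
  psr_u <- psr(fit_u)
  add_csv(summarize_draws(fit_u), "unconditional_parameters.csv")

  fits <- list(unconditional = fit_u)
  cross <- NULL
  for (tr in cfg$tracts) {
    for (with_age in c(FALSE, TRUE)) {
      tag <- paste0(tr, if (with_age) "_age" else "")
      say("fitting conditional model: ", tag)
      ds <- dataset
      cv <- ds$covariates
      cv$fa <- cv[[tr]]
      ds$covariates <- cv[, c("person_id", "fa",
                              if ("age" %in% names(cv)) "age")]
      spec_c <- cfg$spec
      spec_c$include_covariates <- c(fa = TRUE, age = with_age)
      f <- stage(paste0("conditional_fit_", tag),
                 dsem_fit(ds, spec_c, cfg$config, cfg$prior))
      fits[[tag]] <- f
      tab <- summarize_draws(f)
      add_csv(tab, paste0("conditional_", tag, "_parameters.csv"))
      covpar <- grep("^(gamma[0-2][12]|omega[12])$", tab$parameter)
      ptab <- tab[covpar, c("parameter", "estimate", "sd_post")]
      ptab$p <- p_from_posterior(ptab$estimate, ptab$sd_post)
      ptab$p_adj <- fdr_adjust(ptab$p)
      add_csv(ptab, paste0("conditional_", tag, "_pvalues.csv"))
      if (with_age) {
        w1 <- tab[tab$parameter == "omega1", ]
        cross <- rbind(cross, data.frame(tract = tr, omega1 = w1$estimate,
                                         sd_post = w1$sd_post,
                                         lower = w1$lower, upper = w1$upper))
      }
    }
  }
  if (!is.null(cross)) add_csv(cross, "cross_tract_omega1.csv")

  # monitored draws, long format
  dr <- flat_draws(fit_u)
  add_csv(data.frame(draw = seq_len(nrow(dr)), dr), "unconditional_draws.csv")

  summary_json <- list(
    seed = cfg$config$seed, config_hash = stamp$hash,
    n_persons = n_person, n_trial_rows = nrow(dataset$trials),
    n_covariate_observed = n_obs_cov,
    fa_outliers_removed = if (!is.null(screen_report))
      sum(screen_report$n_removed) else 0L,
    psr_max_unconditional = max(psr_u),
    psr_converged = isTRUE(attr(psr_u, "converged")),
    models = names(fits))
  jp <- file.path(cfg$output_dir, "summary.json")
  jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, digits = NA)
  paths[["summary.json"]] <- jp

  manifest <- data.frame(artifact = names(paths),
                         path = unname(unlist(paths)),
                         config_hash = stamp$hash, seed = stamp$seed)
  mp <- file.path(cfg$output_dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  paths[["manifest.csv"]] <- mp
  say("PSR (unconditional) max: ", round(max(psr_u), 3))

  invisible(list(fits = fits, screen_report = screen_report,
                 cross_tract = cross, paths = paths, psr = psr_u,
                 config_hash = stamp$hash))
}
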