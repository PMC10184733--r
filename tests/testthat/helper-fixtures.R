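# Shared fixtures, all generated in code.

# small, fast population: fewer trials, same structure as the defaults
small_pop <- function(n_trials = 20, conditional = FALSE) {
  pop <- default_population(conditional = conditional)
  pop$n_trials <- as.integer(n_trials)
  pop
}

# independently coded brute-force log-density: explicit per-trial normal
# density product, no shared code with conditional_loglik()
brute_force_loglik <- function(y, trials, mu, phi, bt, psi) {
  ll <- 0
  for (t in 2:length(y)) {
    m <- mu + phi * y[t - 1] + bt * trials[t]
    ll <- ll + log(1 / sqrt(2 * pi * psi) * exp(-(y[t] - m)^2 / (2 * psi)))
  }
  ll
}

# random valid person effects
random_effects <- function() {
  person_effects(mu = rnorm(1, -0.9, 0.3), phi = runif(1, -0.6, 0.6),
                 bt = rnorm(1, 0, 0.003), psi = exp(rnorm(1, -3.3, 0.5)))
}

# minimal dsem_fit-shaped object for summary-level functions that only
# touch $eta, $data, $spec (documented draw layout: iter x chain x n x 4)
fake_fit <- function(y_list, eta_draws, spec = model_spec()) {
  structure(list(
    eta = eta_draws,
    draws = NULL,
    data = list(ids = seq_along(y_list), y = y_list,
                trial = lapply(y_list, seq_along),
                cov_names = character(0)),
    spec = spec,
    config = mcmc_config(n_iter = 2, n_burn = 1)), class = "dsem_fit")
}
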