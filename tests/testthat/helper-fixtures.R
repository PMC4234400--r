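# shared fixtures: reduced MCMC settings for desk-scale property runs and a
# toy truth object with equal 0.5/0.5 marginals at every dose

mcmc_quick <- function() mcmc_config(burn_in = 600L, retained = 400L)

toy_truth <- function(pi_T = 0.5, pi_E = 0.5, K = 4L) {
  structure(list(id = 0L,
                 doses = data.frame(dose = seq_len(K), pi_T = pi_T,
                                    pi_E = pi_E),
                 optimal = NA_integer_, futility_optimal = FALSE),
            class = "scenario_truth")
}

# posterior_draws object with prescribed draws, for exercising the
# summary/decision layers without running the sampler
fake_draws <- function(draws, family) {
  structure(list(draws = draws, family = family,
                 acceptance = NA_real_, scales = NA_real_,
                 ess = rep(nrow(draws), ncol(draws)),
                 config = mcmc_quick(), seed = NULL),
            class = "posterior_draws")
}

# grid of strictly interior marginal pairs used by property loops
pair_grid <- function() {
  expand.grid(pi_T = c(0.02, 0.27, 0.5, 0.79, 0.97),
              pi_E = c(0.05, 0.38, 0.5, 0.71, 0.95))
}
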