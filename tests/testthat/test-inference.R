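test_that("log-likelihood matches the joint model cell by cell", {
  p <- marginal_params(-3, 0.8, -1, 0.7, 0.05)
  grid <- dose_grid(4)
  d1 <- trial_data(1, 1, 1, grid)
  cur <- marginal_curves(p, grid)
  expect_equal(log_likelihood(p, copula_spec("independence"), d1),
               log(cur$pi_T[1]) + log(cur$pi_E[1]), tolerance = 1e-12)
  # family collapse carries over to the likelihood
  set.seed(1)
  d <- trial_data(sample(1:4, 30, TRUE), rbinom(30, 1, 0.3),
                  rbinom(30, 1, 0.5), grid)
  expect_equal(log_likelihood(p, copula_spec("braun", 0.5), d),
               log_likelihood(p, copula_spec("independence"), d),
               tolerance = 1e-12)
})

test_that("count-based likelihood equals the per-subject loop oracle", {
  set.seed(7)
  grid <- dose_grid(4)
  d <- trial_data(rep(1:4, each = 11), rbinom(44, 1, 0.3),
                  rbinom(44, 1, 0.6), grid)
  p <- marginal_params(-2.5, 0.9, -1.2, 0.6, -0.1)
  for (cs in list(copula_spec("braun", 0.7), copula_spec("gumbel", 0.4),
                  copula_spec("independence"))) {
    cur <- marginal_curves(p, grid)
    oracle <- sum(vapply(seq_len(nrow(d)), function(i) {
      tab <- joint_table(cur$pi_T[d$dose[i]], cur$pi_E[d$dose[i]], cs)
      idx <- if (d$y_T[i] == 1) (if (d$y_E[i] == 1) 1 else 2) else
        (if (d$y_E[i] == 1) 3 else 4)
      log(tab[idx])
    }, numeric(1)))
    expect_equal(log_likelihood(p, cs, d), oracle, tolerance = 1e-10)
  }
  # count sufficiency: any permutation of records gives the same value
  perm <- sample(nrow(d))
  dp <- trial_data(d$dose[perm], d$y_T[perm], d$y_E[perm], grid)
  expect_identical(log_likelihood(p, copula_spec("braun", 0.7), d),
                   log_likelihood(p, copula_spec("braun", 0.7), dp))
})

test_that("prior presets have the stated moments and support", {
  ps1 <- prior_spec("PS1")
  expect_equal(ps1$slope_shape / ps1$slope_rate, 1)            # mean
  expect_equal(sqrt(ps1$slope_shape) / ps1$slope_rate, 2)      # sd
  ps3 <- prior_spec("PS3")
  expect_equal(ps3$slope_shape / ps3$slope_rate, 1)
  expect_equal(sqrt(ps3$slope_shape) / ps3$slope_rate, 5)
  expect_equal(prior_spec("PS2")$b0T_sd, 5)
  expect_equal(prior_spec("PS4")$b0E_sd, 5)
  expect_equal(prior_spec("PS4")$slope_rate, 1 / 25)

  p <- marginal_params(-3, 1, -1, 1, 0)
  expect_equal(log_prior(p, copula_spec("independence"), ps1),
               dnorm(-3, -3, 3, log = TRUE) + dnorm(-1, -1, 3, log = TRUE) +
                 dnorm(0, 0, 0.25, log = TRUE) +
                 2 * dgamma(1, 1 / 4, 1 / 4, log = TRUE),
               tolerance = 1e-12)
  # flat gumbel prior contributes log(1/2); braun contributes 0
  expect_equal(log_prior(p, copula_spec("gumbel", 0.3), ps1) -
                 log_prior(p, copula_spec("braun", 0.3), ps1), log(0.5))
  expect_identical(log_prior(p, structure(list(family = "braun", psi = 1.5),
                                          class = "copula_spec"), ps1), -Inf)
})

test_that("sampler is deterministic under a fixed seed and respects support", {
  set.seed(5)
  grid <- dose_grid(4)
  d <- trial_data(rep(1:4, each = 11), rbinom(44, 1, 0.25),
                  rbinom(44, 1, 0.55), grid)
  f1 <- sample_posterior(d, "braun", mcmc = mcmc_quick(), seed = 99)
  f2 <- sample_posterior(d, "braun", mcmc = mcmc_quick(), seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$draws[, "beta1_T"] > 0))
  expect_true(all(f1$draws[, "beta1_E"] > 0))
  expect_true(all(f1$draws[, "psi"] > 0 & f1$draws[, "psi"] < 1))
  expect_equal(nrow(f1$draws), 400L)

  fg <- sample_posterior(d, "gumbel", mcmc = mcmc_quick(), seed = 99)
  expect_true(all(fg$draws[, "psi"] > -1 & fg$draws[, "psi"] < 1))

  # post-adaptation acceptance rates within the working band
  f3 <- sample_posterior(d, "braun", seed = 7)
  expect_true(all(f3$acceptance >= 0.1 & f3$acceptance <= 0.6))

  expect_warning(sample_posterior(trial_data(rep(1, 6), rbinom(6, 1, .3),
                                             rbinom(6, 1, .5), grid),
                                  "independence", mcmc = mcmc_quick(),
                                  warn_empty = TRUE),
                 "no observations")
})

test_that("posterior agrees with an exact grid posterior on a reduced problem", {
  # single-dose data: under independence the intercept posteriors are
  # 1-D and exactly integrable
  set.seed(3)
  n <- 40
  yT <- rbinom(n, 1, 0.2); yE <- rbinom(n, 1, 0.6)
  d <- trial_data(rep(1, n), yT, yE, dose_grid(4))
  fit <- sample_posterior(d, "independence", seed = 11,
                          mcmc = mcmc_config(4000, 4000))
  grid_mean <- function(nsucc, n, m, s) {
    b <- seq(-15, 15, length.out = 20001)
    lp <- dnorm(b, m, s, log = TRUE) + nsucc * plogis(b, log.p = TRUE) +
      (n - nsucc) * plogis(-b, log.p = TRUE)
    w <- exp(lp - max(lp))
    sum(b * w) / sum(w)
  }
  expect_equal(mean(fit$draws[, "beta0_T"]), grid_mean(sum(yT), n, -3, 3),
               tolerance = 0.02)
  expect_equal(mean(fit$draws[, "beta0_E"]), grid_mean(sum(yE), n, -1, 3),
               tolerance = 0.02)
})

test_that("prior-only sampling recovers the prior", {
  d <- trial_data(1, 0, 0, dose_grid(4))  # ignored under prior_only
  fit <- sample_posterior(d, "braun", mcmc = mcmc_config(3000, 8000),
                          seed = 21, prior_only = TRUE)
  m <- colMeans(fit$draws)
  s <- apply(fit$draws, 2, sd)
  # intercepts N(-3,3), N(-1,3); quadratic N(0,0.25); slopes mean 1 sd 2;
  # psi uniform(0,1) mean 0.5 sd sqrt(1/12); tolerances ~ a few MCSE
  expect_equal(unname(m[c("beta0_T", "beta0_E", "beta2_E")]), c(-3, -1, 0),
               tolerance = 0.35)
  expect_equal(unname(s[c("beta0_T", "beta0_E")]), c(3, 3), tolerance = 0.1)
  expect_equal(unname(s["beta2_E"]), 0.25, tolerance = 0.1)
  expect_equal(unname(m[c("beta1_T", "beta1_E")]), c(1, 1), tolerance = 0.35)
  expect_equal(unname(s[c("beta1_T", "beta1_E")]), c(2, 2), tolerance = 0.3)
  expect_equal(unname(m["psi"]), 0.5, tolerance = 0.05)
  expect_equal(unname(s["psi"]), sqrt(1 / 12), tolerance = 0.05)
})

test_that("posterior dose summaries map draws to marginals", {
  dm <- cbind(beta0_T = -3, beta1_T = 1e-9, beta0_E = -1, beta1_E = 1e-9,
              beta2_E = 0)
  s <- posterior_dose_summaries(fake_draws(dm, "independence"), dose_grid(4))
  expect_equal(unname(s$pi_T[1, ]), rep(plogis(-3), 4), tolerance = 1e-6)

  # braun psi = 0.5: corrected marginals coincide with the logistic ones
  dm2 <- cbind(dm, psi = 0.5)
  s2 <- posterior_dose_summaries(fake_draws(dm2, "braun"), dose_grid(4))
  expect_equal(s2$pi_T, s$pi_T, tolerance = 1e-12)

  # braun psi = 0.9: matches joint-table cell sums at that draw
  dm3 <- cbind(beta0_T = 0, beta1_T = 1e-9, beta0_E = 0, beta1_E = 1e-9,
               beta2_E = 0, psi = 0.9)
  s3 <- posterior_dose_summaries(fake_draws(dm3, "braun"), dose_grid(2))
  tab <- joint_table(0.5, 0.5, copula_spec("braun", 0.9))
  expect_equal(unname(s3$pi_T[1, 1]), unname(tab["p11"] + tab["p10"]),
               tolerance = 1e-8)
})

test_that("parameter recovery at n = 2000 under independence", {
  set.seed(42)
  truth <- marginal_params(-3, 1, -1, 0.8, 0.05)
  grid <- dose_grid(4)
  cur <- marginal_curves(truth, grid)
  doses <- rep(1:4, each = 500)
  d <- trial_data(doses, rbinom(2000, 1, cur$pi_T[doses]),
                  rbinom(2000, 1, cur$pi_E[doses]), grid)
  fit <- sample_posterior(d, "independence", seed = 7)
  m <- colMeans(fit$draws)
  s <- apply(fit$draws, 2, sd)
  tv <- unlist(truth)
  for (nm in names(tv))
    expect_lt(abs(m[nm] - tv[nm]) / s[nm], 3)
})
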