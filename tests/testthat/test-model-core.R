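test_that("marginal curves follow the logistic predictors", {
  # intercept-only: dose-1 probabilities are the inverse-logit intercepts
  p <- marginal_params(-3, 1e-9, -1, 1e-9, 0)
  cur <- marginal_curves(p, dose_grid(4))
  expect_equal(cur$pi_T[1], plogis(-3), tolerance = 1e-12)
  expect_equal(round(cur$pi_T[1], 2), 0.05)
  expect_equal(cur$pi_E[1], plogis(-1), tolerance = 1e-12)
  expect_equal(round(cur$pi_E[1], 2), 0.27)

  p2 <- marginal_params(0, 1e-12, 0, 1e-12, 0)
  expect_equal(marginal_curves(p2, dose_grid(3))$pi_T, rep(0.5, 3))

  # toxicity monotone non-decreasing for any positive slope
  p3 <- marginal_params(-2, 0.7, -1, 0.5, -0.4)
  expect_true(all(diff(marginal_curves(p3, dose_grid(6))$pi_T) >= 0))
})

test_that("marginal_params enforces positive slopes", {
  expect_error(marginal_params(-3, -0.1, -1, 1), "slopes")
  expect_error(marginal_params(-3, 1, -1, 0), "slopes")
})

test_that("copula_spec validates the association parameter", {
  expect_error(copula_spec("braun", 1.2), "braun")
  expect_error(copula_spec("braun", 0), "braun")
  expect_error(copula_spec("gumbel", -1), "gumbel")
  expect_error(copula_spec("independence", 0.3), "no association")
  expect_silent(copula_spec("gumbel", -0.99))
})

test_that("joint_table reproduces worked examples", {
  # braun (0.5, 0.5, psi1 = 0.9): unnormalised masses (.225,.025,.025,.025)
  tab <- joint_table(0.5, 0.5, copula_spec("braun", 0.9))
  expect_equal(unname(tab), c(0.225, 0.025, 0.025, 0.025) / 0.3,
               tolerance = 1e-12)
  # gumbel (0.5, 0.5, psi2 = 0.8): product cells 0.25 +/- 0.0625 * 0.8
  tab <- joint_table(0.5, 0.5, copula_spec("gumbel", 0.8))
  expect_equal(unname(tab), c(0.30, 0.20, 0.20, 0.30), tolerance = 1e-12)
})

test_that("joint tables normalise and collapse across families", {
  g <- pair_grid()
  for (i in seq_len(nrow(g))) {
    pT <- g$pi_T[i]; pE <- g$pi_E[i]
    indep <- joint_table(pT, pE, copula_spec("independence"))
    for (psi in c(0.1, 0.5, 0.7, 0.9)) {
      tab <- joint_table(pT, pE, copula_spec("braun", psi))
      expect_equal(sum(tab), 1, tolerance = 1e-12)
      expect_true(all(tab >= 0))
      # odds-ratio identity: p11 p00 / (p10 p01) = psi/(1-psi) exactly
      expect_equal(tab["p11"] * tab["p00"] / (tab["p10"] * tab["p01"]),
                   c(p11 = psi / (1 - psi)), tolerance = 1e-12)
    }
    for (psi in c(-0.8, -0.3, 0, 0.4, 0.8)) {
      tab <- joint_table(pT, pE, copula_spec("gumbel", psi))
      expect_equal(sum(tab), 1, tolerance = 1e-12)
      expect_true(all(tab >= 0))
      # gumbel preserves its input marginals exactly
      expect_equal(unname(tab["p11"] + tab["p10"]), pT, tolerance = 1e-15)
      expect_equal(unname(tab["p11"] + tab["p01"]), pE, tolerance = 1e-15)
    }
    # family collapse at the independence point
    expect_equal(joint_table(pT, pE, copula_spec("braun", 0.5)), indep,
                 tolerance = 1e-15)
    expect_equal(joint_table(pT, pE, copula_spec("gumbel", 0)), indep,
                 tolerance = 1e-15)
  }
})

test_that("braun true marginals equal joint-table cell sums", {
  expect_equal(braun_true_marginals(0.5, 0.5, 0.9),
               c(pi_T = 5 / 6, pi_E = 5 / 6), tolerance = 1e-12)
  # psi1 = 0.5: parameters are the marginals
  expect_equal(braun_true_marginals(0.27, 0.71, 0.5),
               c(pi_T = 0.27, pi_E = 0.71), tolerance = 1e-15)
  g <- pair_grid()
  for (i in seq_len(nrow(g))) {
    for (psi in c(0.2, 0.5, 0.7, 0.9)) {
      tab <- joint_table(g$pi_T[i], g$pi_E[i], copula_spec("braun", psi))
      tm <- braun_true_marginals(g$pi_T[i], g$pi_E[i], psi)
      expect_equal(unname(tm["pi_T"]), unname(tab["p11"] + tab["p10"]),
                   tolerance = 1e-12)
      expect_equal(unname(tm["pi_E"]), unname(tab["p11"] + tab["p01"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("conditional probabilities agree with joint-table ratios", {
  # braun given y_T = 0 reduces to pi_E for any psi1
  expect_equal(conditional_prob(0.3, 0.6, copula_spec("braun", 0.8), 0), 0.6,
               tolerance = 1e-12)
  expect_equal(conditional_prob(0.3, 0.6, copula_spec("gumbel", 0), 1), 0.6,
               tolerance = 1e-15)
  expect_equal(conditional_prob(0.5, 0.5, copula_spec("braun", 0.9), 1), 0.9,
               tolerance = 1e-12)
  g <- pair_grid()
  specs <- list(copula_spec("braun", 0.7), copula_spec("braun", 0.2),
                copula_spec("gumbel", 0.6), copula_spec("gumbel", -0.5))
  for (i in seq_len(nrow(g))) {
    pT <- g$pi_T[i]; pE <- g$pi_E[i]
    for (cs in specs) {
      tab <- joint_table(pT, pE, cs)
      pT_marg <- unname(tab["p11"] + tab["p10"])
      # conditional x toxicity marginal reconstructs the joint cells
      c1 <- conditional_prob(pT, pE, cs, 1)
      c0 <- conditional_prob(pT, pE, cs, 0)
      expect_equal(unname(tab["p11"]), c1 * pT_marg, tolerance = 1e-12)
      expect_equal(unname(tab["p01"]), c0 * (1 - pT_marg), tolerance = 1e-12)
    }
  }
})

test_that("braun marginal inversion round-trips", {
  expect_equal(invert_braun_marginals(5 / 6, 5 / 6, 0.9),
               c(pi_T = 0.5, pi_E = 0.5), tolerance = 1e-10)
  expect_equal(invert_braun_marginals(0.27, 0.71, 0.5),
               c(pi_T = 0.27, pi_E = 0.71), tolerance = 1e-12)
  targets <- expand.grid(tT = c(0.05, 0.27, 0.5, 0.83),
                         tE = c(0.12, 0.43, 0.71, 0.9))
  for (i in seq_len(nrow(targets))) {
    for (psi in c(0.5, 0.7, 0.9)) {
      par <- invert_braun_marginals(targets$tT[i], targets$tE[i], psi)
      back <- braun_true_marginals(par[["pi_T"]], par[["pi_E"]], psi)
      expect_equal(unname(back), c(targets$tT[i], targets$tE[i]),
                   tolerance = 1e-8)
    }
  }
})
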