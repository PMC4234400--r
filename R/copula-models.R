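#' Dose grid of ordered integer dose indices
#'
#' Doses are coded by consecutive integer indices starting at 1; the linear
#' predictors of the marginal models use `z - 1`, so the intercepts are the
#' log-odds of toxicity / efficacy at the first dose level.
#'
#' @param n_doses Number of dose levels (default 4).
#' @return Integer vector of class `dose_grid`, `1:n_doses`.
#' @export
dose_grid <- function(n_doses = 4L) {
  n_doses <- as.integer(n_doses)
  if (length(n_doses) != 1L || is.na(n_doses) || n_doses < 1L)
    stop("`n_doses` must be a positive integer", call. = FALSE)
  structure(seq_len(n_doses), class = "dose_grid")
}

#' Marginal dose-response parameters
#'
#' The five regression coefficients of the logistic dose-toxicity and
#' dose-efficacy models:
#' \deqn{logit \pi_T(z) = \beta_{0,T} + \beta_{1,T}(z-1)}
#' \deqn{logit \pi_E(z) = \beta_{0,E} + \beta_{1,E}(z-1) + \beta_{2,E}(z-1)^2}
#' Positive slopes are required (the support of their Gamma priors), so the
#' marginal probability of toxicity is monotonically increasing in dose; the
#' quadratic term lets efficacy level off or turn over.
#'
#' @param beta0_T,beta1_T Toxicity intercept (log-odds at dose 1) and slope.
#' @param beta0_E,beta1_E,beta2_E Efficacy intercept, slope and quadratic
#'   coefficient.
#' @return A `marginal_params` list.
#' @export
marginal_params <- function(beta0_T, beta1_T, beta0_E, beta1_E, beta2_E = 0) {
  vals <- c(beta0_T = beta0_T, beta1_T = beta1_T, beta0_E = beta0_E,
            beta1_E = beta1_E, beta2_E = beta2_E)
  if (any(!is.finite(vals)))
    stop("all coefficients must be finite", call. = FALSE)
  if (beta1_T <= 0 || beta1_E <= 0)
    stop("slopes beta1_T and beta1_E must be > 0", call. = FALSE)
  structure(as.list(vals), class = "marginal_params")
}

#' Joint-model (copula) specification
#'
#' @param family One of `"braun"`, `"gumbel"`, `"independence"`.
#' @param psi Association parameter: `psi1` in (0,1) for the Braun model
#'   (0.5 = independence, `psi1/(1-psi1)` is the toxicity-efficacy odds
#'   ratio); `psi2` in (-1,1) for the Gumbel-Morgenstern model (0 =
#'   independence). Omitted for `"independence"`.
#' @return A `copula_spec` list with elements `family` and `psi`.
#' @export
copula_spec <- function(family = c("braun", "gumbel", "independence"),
                        psi = NULL) {
  family <- match.arg(family)
  if (family == "independence") {
    if (!is.null(psi))
      stop("the independence model carries no association parameter",
           call. = FALSE)
  } else {
    if (is.null(psi) || length(psi) != 1L || !is.finite(psi))
      stop(sprintf("the %s family requires a scalar `psi`", family),
           call. = FALSE)
    if (family == "braun" && (psi <= 0 || psi >= 1))
      stop("braun psi1 must lie in the open interval (0, 1)", call. = FALSE)
    if (family == "gumbel" && (psi <= -1 || psi >= 1))
      stop("gumbel psi2 must lie in the open interval (-1, 1)", call. = FALSE)
  }
  structure(list(family = family, psi = psi), class = "copula_spec")
}

expit <- function(x) stats::plogis(x)

check_pair <- function(pi_T, pi_E) {
  if (any(pi_T <= 0 | pi_T >= 1) || any(pi_E <= 0 | pi_E >= 1))
    stop("marginal probabilities must lie strictly inside (0, 1)",
         call. = FALSE)
}

#' Marginal toxicity and efficacy curves over a dose grid
#'
#' @param params A [marginal_params()] object.
#' @param grid A [dose_grid()] (or integer vector of dose indices).
#' @return `data.frame` with columns `dose`, `pi_T`, `pi_E`.
#' @export
marginal_curves <- function(params, grid = dose_grid()) {
  stopifnot(inherits(params, "marginal_params"))
  z <- as.integer(grid)
  if (length(z) == 0L) stop("empty dose grid", call. = FALSE)
  x <- z - 1
  data.frame(
    dose = z,
    pi_T = expit(params$beta0_T + params$beta1_T * x),
    pi_E = expit(params$beta0_E + params$beta1_E * x + params$beta2_E * x^2)
  )
}

#' Joint 2x2 probability table of (toxicity, efficacy) at one dose
#'
#' Builds the joint distribution of the binary pair `(Y_T, Y_E)` from the
#' marginal-model probabilities and the chosen joint model.
#'
#' * Braun (Arnold-Strauss): cell mass proportional to
#'   `pi_E^yE (1-pi_E)^(1-yE) pi_T^yT (1-pi_T)^(1-yT) psi1^(yT yE)
#'   (1-psi1)^(1-yT yE)`, normalised by
#'   `k = 1 / ((1-psi1)(1 - pi_T pi_E) + psi1 pi_T pi_E)`. Note `pi_T`,
#'   `pi_E` are *not* the marginals of the table unless `psi1 = 0.5`; see
#'   [braun_true_marginals()].
#' * Gumbel (Morgenstern): product cell plus
#'   `(-1)^(yE+yT) pi_E(1-pi_E) pi_T(1-pi_T) psi2`; the input marginals are
#'   preserved exactly, and all cells are nonnegative for any |psi2| < 1.
#' * Independence: the outer product.
#'
#' @param pi_T,pi_E Marginal-model probabilities, strictly in (0,1).
#' @param copula A [copula_spec()].
#' @return Named numeric vector `c(p11, p10, p01, p00)` of probabilities of
#'   `(y_T, y_E)` = (1,1), (1,0), (0,1), (0,0); sums to 1.
#' @export
joint_table <- function(pi_T, pi_E, copula) {
  stopifnot(inherits(copula, "copula_spec"))
  check_pair(pi_T, pi_E)
  tab <- switch(copula$family,
    independence = c(p11 = pi_T * pi_E,
                     p10 = pi_T * (1 - pi_E),
                     p01 = (1 - pi_T) * pi_E,
                     p00 = (1 - pi_T) * (1 - pi_E)),
    braun = {
      psi <- copula$psi
      k <- 1 / ((1 - psi) * (1 - pi_T * pi_E) + psi * pi_T * pi_E)
      c(p11 = k * pi_T * pi_E * psi,
        p10 = k * pi_T * (1 - pi_E) * (1 - psi),
        p01 = k * (1 - pi_T) * pi_E * (1 - psi),
        p00 = k * (1 - pi_T) * (1 - pi_E) * (1 - psi))
    },
    gumbel = {
      d <- pi_E * (1 - pi_E) * pi_T * (1 - pi_T) * copula$psi
      tab <- c(p11 = pi_T * pi_E + d,
               p10 = pi_T * (1 - pi_E) - d,
               p01 = (1 - pi_T) * pi_E - d,
               p00 = (1 - pi_T) * (1 - pi_E) + d)
      if (any(tab < 0))
        stop("gumbel parameter combination yields a negative cell",
             call. = FALSE)
      tab
    })
  tab
}

#' True marginals implied by the Braun copula parameters
#'
#' In the Braun model the parameters `pi_T`, `pi_E` are conditional-scale
#' quantities: the realised marginals of the joint table are
#' `Pr(Y_T = 1) = k pi_T ((1-pi_E)(1-psi1) + pi_E psi1)` and analogously for
#' efficacy, equal to the parameters only at `psi1 = 0.5`. This matters for
#' dose finding and for simulating data with prescribed true marginals.
#'
#' @inheritParams joint_table
#' @param psi1 Braun association parameter in (0,1).
#' @return Named vector `c(pi_T, pi_E)` of the realised marginals.
#' @export
braun_true_marginals <- function(pi_T, pi_E, psi1) {
  check_pair(pi_T, pi_E)
  if (any(psi1 <= 0 | psi1 >= 1))
    stop("psi1 must lie in (0, 1)", call. = FALSE)
  k <- 1 / ((1 - psi1) * (1 - pi_T * pi_E) + psi1 * pi_T * pi_E)
  c(pi_T = k * pi_T * ((1 - pi_E) * (1 - psi1) + pi_E * psi1),
    pi_E = k * pi_E * ((1 - pi_T) * (1 - psi1) + pi_T * psi1))
}

#' Conditional probability of efficacy given the toxicity outcome
#'
#' `Pr(Y_E = 1 | Y_T = y_T)` under the chosen joint model, via the closed
#' forms: Braun
#' `pi_E psi1^yT (1-psi1)^(1-yT) / (pi_E psi1^yT (1-psi1)^(1-yT) +
#' (1-psi1)(1-pi_E))`; Gumbel
#' `pi_E + (-1)^(1+yT) pi_E (1-pi_E) pi_T^(1-yT) (1-pi_T)^yT psi2`.
#'
#' @inheritParams joint_table
#' @param given_yT Conditioning toxicity outcome, 0 or 1.
#' @return Scalar probability.
#' @export
conditional_prob <- function(pi_T, pi_E, copula, given_yT) {
  stopifnot(inherits(copula, "copula_spec"), given_yT %in% c(0, 1))
  check_pair(pi_T, pi_E)
  switch(copula$family,
    independence = pi_E,
    braun = {
      psi <- copula$psi
      w <- pi_E * psi^given_yT * (1 - psi)^(1 - given_yT)
      w / (w + (1 - psi) * (1 - pi_E))
    },
    gumbel = {
      psi <- copula$psi
      pi_E + (-1)^(1 + given_yT) *
        pi_E * (1 - pi_E) * pi_T^(1 - given_yT) * (1 - pi_T)^given_yT * psi
    })
}

#' Braun copula parameters matching prescribed true marginals
#'
#' Inverse of [braun_true_marginals()]: finds the `(pi_T, pi_E)` parameters
#' whose Braun joint table at association `psi1` has the given *true*
#' marginals. Uses the fact that a 2x2 table is determined by its margins
#' and odds ratio: the Braun odds ratio is `psi1/(1-psi1)`, so `p11` solves
#' the Plackett quadratic for the target margins, and the copula parameters
#' are read off the cells as `pi_T = p10/(p10+p00)`, `pi_E = p01/(p01+p00)`.
#'
#' @param target_T,target_E Target true marginals, strictly in (0,1).
#' @param psi1 Braun association parameter in (0,1).
#' @return Named vector `c(pi_T, pi_E)` of copula parameters; the forward
#'   map reproduces the targets to well below 1e-8.
#' @export
invert_braun_marginals <- function(target_T, target_E, psi1) {
  check_pair(target_T, target_E)
  if (psi1 <= 0 || psi1 >= 1)
    stop("psi1 must lie in (0, 1)", call. = FALSE)
  theta <- psi1 / (1 - psi1)
  p11 <- p11_from_margins(target_T, target_E, theta)
  p10 <- target_T - p11
  p01 <- target_E - p11
  p00 <- 1 - target_T - target_E + p11
  c(pi_T = p10 / (p10 + p00), pi_E = p01 / (p01 + p00))
}

# p11 of the 2x2 table with margins (pT, pE) and odds ratio theta
# (Plackett construction); stable root of the quadratic.
p11_from_margins <- function(pT, pE, theta) {
  if (abs(theta - 1) < 1e-12) return(pT * pE)
  a <- theta - 1
  b <- 1 + (pT + pE) * a
  # a*p^2 - b*p + theta*pT*pE = 0; the valid root lies in
  # (max(0, pT+pE-1), min(pT, pE))
  disc <- b^2 - 4 * a * theta * pT * pE
  # the (b - sqrt)/(2a) root lies in (max(0, pT+pE-1), min(pT, pE)) for
  # every theta > 0, theta != 1
  (b - sqrt(disc)) / (2 * a)
}
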