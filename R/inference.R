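#' Accrued trial data
#'
#' Per-subject records of dose index and the binary (toxicity, efficacy)
#' outcome pair.
#'
#' @param dose Integer dose indices within the grid.
#' @param y_T,y_E Binary outcome vectors (0/1) of the same length.
#' @param grid A [dose_grid()].
#' @return A `trial_data` data.frame with columns `dose`, `y_T`, `y_E`.
#' @export
trial_data <- function(dose, y_T, y_E, grid = dose_grid()) {
  dose <- as.integer(dose)
  if (length(y_T) != length(dose) || length(y_E) != length(dose))
    stop("dose, y_T and y_E must have equal length", call. = FALSE)
  if (!all(dose %in% as.integer(grid)))
    stop("doses outside the dose grid", call. = FALSE)
  if (!all(y_T %in% c(0, 1)) || !all(y_E %in% c(0, 1)))
    stop("outcomes must be binary 0/1", call. = FALSE)
  structure(data.frame(dose = dose, y_T = as.integer(y_T),
                       y_E = as.integer(y_E)),
            grid = as.integer(grid),
            class = c("trial_data", "data.frame"))
}

#' Outcome-count contingency table
#'
#' The likelihood depends on the data only through the per-dose counts of
#' the four (y_T, y_E) outcome combinations; this collapses a `trial_data`
#' to that K x 4 table.
#'
#' @param data A [trial_data()] object.
#' @return Integer matrix with one row per dose and columns
#'   `n11, n10, n01, n00`.
#' @export
outcome_counts <- function(data) {
  grid <- attr(data, "grid")
  if (is.null(grid)) grid <- seq_len(max(data$dose))
  counts <- matrix(0L, nrow = length(grid), ncol = 4L,
                   dimnames = list(paste0("dose", grid),
                                   c("n11", "n10", "n01", "n00")))
  # cell index: (1,1)->1, (1,0)->2, (0,1)->3, (0,0)->4
  cell <- ifelse(data$y_T == 1L, ifelse(data$y_E == 1L, 1L, 2L),
                 ifelse(data$y_E == 1L, 3L, 4L))
  for (i in seq_along(data$dose))
    counts[data$dose[i], cell[i]] <- counts[data$dose[i], cell[i]] + 1L
  counts
}

#' Joint log-likelihood of accrued data
#'
#' Sum over subjects of the log joint-table cell matching the observed
#' (y_T, y_E) at the subject's dose; evaluated from the sufficient
#' count table. Marginal probabilities are clamped away from 0/1 by 1e-12
#' inside this evaluation only; a structurally zero cell carrying a
#' positive count yields `-Inf` (not an error).
#'
#' @param params A [marginal_params()].
#' @param copula A [copula_spec()].
#' @param data A [trial_data()] object (non-empty).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, copula, data) {
  if (nrow(data) == 0L) stop("empty trial data", call. = FALSE)
  counts <- outcome_counts(data)
  grid <- attr(data, "grid")
  if (is.null(grid)) grid <- seq_len(nrow(counts))
  curves <- marginal_curves(params, grid)
  ll <- 0
  for (i in seq_along(grid)) {
    if (sum(counts[i, ]) == 0L) next
    piT <- min(max(curves$pi_T[i], 1e-12), 1 - 1e-12)
    piE <- min(max(curves$pi_E[i], 1e-12), 1 - 1e-12)
    cells <- joint_table(piT, piE, copula)
    if (any(cells == 0 & counts[i, ] > 0)) return(-Inf)
    ll <- ll + sum(counts[i, ] * log(cells))
  }
  ll
}

# preset prior constants: intercept sds and slope gamma hyper-parameters
prior_presets <- list(
  PS1 = list(int_sd = 3, slope = 1 / 4),
  PS2 = list(int_sd = 5, slope = 1 / 4),
  PS3 = list(int_sd = 3, slope = 1 / 25),
  PS4 = list(int_sd = 5, slope = 1 / 25)
)

#' Prior specification
#'
#' Normal priors on the intercepts and the efficacy quadratic coefficient,
#' Gamma priors on the (positive) slopes, and a flat prior on the
#' association parameter over its family interval. The default preset PS1
#' is: `beta0_T ~ N(-3, sd 3)`, `beta0_E ~ N(-1, sd 3)`,
#' `beta2_E ~ N(0, sd 0.25)`, slopes `~ Gamma(1/4, rate 1/4)` (mean 1,
#' sd 2). PS2 widens the intercept sds to 5, PS3 widens the slope priors
#' to `Gamma(1/25, 1/25)` (mean 1, sd 5), PS4 does both.
#'
#' @param preset One of `"PS1"`..`"PS4"`.
#' @param b0T_mean,b0T_sd,b0E_mean,b0E_sd,b2E_mean,b2E_sd,slope_shape,slope_rate
#'   Optional overrides of individual hyper-parameters.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(preset = c("PS1", "PS2", "PS3", "PS4"),
                       b0T_mean = -3, b0T_sd = NULL,
                       b0E_mean = -1, b0E_sd = NULL,
                       b2E_mean = 0, b2E_sd = 0.25,
                       slope_shape = NULL, slope_rate = NULL) {
  preset <- match.arg(preset)
  ps <- prior_presets[[preset]]
  spec <- list(
    preset = preset,
    b0T_mean = b0T_mean, b0T_sd = if (is.null(b0T_sd)) ps$int_sd else b0T_sd,
    b0E_mean = b0E_mean, b0E_sd = if (is.null(b0E_sd)) ps$int_sd else b0E_sd,
    b2E_mean = b2E_mean, b2E_sd = b2E_sd,
    slope_shape = if (is.null(slope_shape)) ps$slope else slope_shape,
    slope_rate = if (is.null(slope_rate)) ps$slope else slope_rate
  )
  with(spec, stopifnot(b0T_sd > 0, b0E_sd > 0, b2E_sd > 0,
                       slope_shape > 0, slope_rate > 0))
  structure(spec, class = "prior_spec")
}

#' Joint log-prior density
#'
#' @param params A [marginal_params()] (or plain list with the five betas).
#' @param copula A [copula_spec()]; for the copula families its `psi` is the
#'   value whose flat prior is evaluated.
#' @param prior A [prior_spec()].
#' @return Scalar log-density; `-Inf` outside the support.
#' @export
log_prior <- function(params, copula, prior = prior_spec()) {
  stopifnot(inherits(prior, "prior_spec"))
  if (params$beta1_T <= 0 || params$beta1_E <= 0) return(-Inf)
  lp <- stats::dnorm(params$beta0_T, prior$b0T_mean, prior$b0T_sd, log = TRUE) +
    stats::dnorm(params$beta0_E, prior$b0E_mean, prior$b0E_sd, log = TRUE) +
    stats::dnorm(params$beta2_E, prior$b2E_mean, prior$b2E_sd, log = TRUE) +
    stats::dgamma(params$beta1_T, prior$slope_shape, prior$slope_rate,
                  log = TRUE) +
    stats::dgamma(params$beta1_E, prior$slope_shape, prior$slope_rate,
                  log = TRUE)
  if (copula$family == "braun") {
    if (copula$psi <= 0 || copula$psi >= 1) return(-Inf)
  } else if (copula$family == "gumbel") {
    if (copula$psi <= -1 || copula$psi >= 1) return(-Inf)
    lp <- lp + log(0.5)
  }
  lp
}

#' MCMC configuration
#'
#' @param burn_in Burn-in iterations (default 5000, during which proposal
#'   scales adapt).
#' @param retained Retained post-burn-in draws (default 1000).
#' @param thin Thinning interval (default 1).
#' @param adapt_interval Iterations between proposal-scale adaptations
#'   during burn-in.
#' @param target_acceptance Per-block acceptance rate targeted by the
#'   adaptation (default 0.35).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(burn_in = 5000L, retained = 1000L, thin = 1L,
                        adapt_interval = 100L, target_acceptance = 0.35) {
  cfg <- list(burn_in = as.integer(burn_in), retained = as.integer(retained),
              thin = as.integer(thin),
              adapt_interval = as.integer(adapt_interval),
              target_acceptance = target_acceptance)
  if (cfg$burn_in < 0L || cfg$retained < 1L || cfg$thin < 1L ||
      cfg$adapt_interval < 1L ||
      target_acceptance <= 0 || target_acceptance >= 1)
    stop("invalid MCMC configuration", call. = FALSE)
  structure(cfg, class = "mcmc_config")
}

family_code <- function(family) {
  match(family, c("independence", "braun", "gumbel")) - 1L
}

#' Posterior sampling by adaptive Metropolis-within-Gibbs
#'
#' Samples the joint posterior of the marginal-model coefficients (and, for
#' the copula families, the association parameter) given accrued trial
#' data. Parameters are updated in three random-walk blocks — toxicity
#' (intercept, log-slope), efficacy (intercept, log-slope, quadratic) and
#' association (logit-type transform) — with Gaussian proposals whose
#' scales adapt toward the target acceptance rate during burn-in only, so
#' the retained chain is Markov. Slopes are sampled on the log scale and
#' the association on a logit scale, with the Jacobian terms included.
#'
#' @param data A [trial_data()] object, non-empty.
#' @param copula_family `"independence"`, `"braun"` or `"gumbel"` (the
#'   model being *fit*; its association parameter is estimated).
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param seed Optional integer seed (`set.seed` before sampling); `NULL`
#'   continues the current RNG stream.
#' @param prior_only If `TRUE`, the likelihood is switched off and the
#'   chain targets the prior (used for validation).
#' @param warn_empty Warn when some dose arm has no observations (normal in
#'   early trial interims; suppressed inside the trial engine).
#' @return A `posterior_draws` object: `draws` (matrix, one named column
#'   per parameter on the natural scale), per-block post-adaptation
#'   `acceptance` rates, adapted proposal `scales`, a crude effective
#'   sample size per parameter, the configuration and seed.
#' @export
sample_posterior <- function(data,
                             copula_family = c("independence", "braun",
                                               "gumbel"),
                             prior = prior_spec(), mcmc = mcmc_config(),
                             seed = NULL, prior_only = FALSE,
                             warn_empty = FALSE) {
  copula_family <- match.arg(copula_family)
  stopifnot(inherits(prior, "prior_spec"), inherits(mcmc, "mcmc_config"))
  if (nrow(data) == 0L && !prior_only)
    stop("empty trial data", call. = FALSE)
  counts <- outcome_counts(data)
  if (warn_empty && any(rowSums(counts) == 0L))
    warning("some dose arms carry no observations; their marginals are ",
            "informed by the model and priors only", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  prior_vec <- c(prior$b0T_mean, prior$b0T_sd, prior$b0E_mean, prior$b0E_sd,
                 prior$b2E_mean, prior$b2E_sd, prior$slope_shape,
                 prior$slope_rate)
  fit <- mcmc_sampler_cpp(counts, family_code(copula_family), prior_vec,
                          mcmc$burn_in, mcmc$retained, mcmc$thin,
                          mcmc$adapt_interval, mcmc$target_acceptance,
                          isTRUE(prior_only))
  draws <- fit$draws
  nms <- c("beta0_T", "beta1_T", "beta0_E", "beta1_E", "beta2_E")
  if (copula_family != "independence") nms <- c(nms, "psi")
  colnames(draws) <- nms
  structure(list(draws = draws, family = copula_family,
                 acceptance = as.numeric(fit$acceptance),
                 scales = as.numeric(fit$scales),
                 ess = apply(draws, 2, ess_lag1),
                 config = mcmc, seed = seed, prior = prior),
            class = "posterior_draws")
}

# crude AR(1)-based effective sample size, logged for diagnostics
ess_lag1 <- function(x) {
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) return(n)
  r1 <- stats::cor(x[-1], x[-n])
  if (!is.finite(r1)) return(n)
  r1 <- min(max(r1, -0.999), 0.999)
  max(1, n * (1 - r1) / (1 + r1))
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws (", x$family, " model): ", nrow(x$draws),
      " retained x ", ncol(x$draws), " parameters\n", sep = "")
  cat("block acceptance:", paste(sprintf("%.2f", x$acceptance),
                                 collapse = " "), "\n")
  print(round(rbind(mean = colMeans(x$draws),
                    sd = apply(x$draws, 2, stats::sd),
                    ess = x$ess), 3))
  invisible(x)
}

#' Per-dose posterior draws of the marginal probabilities
#'
#' Maps each retained parameter draw to the marginal toxicity and efficacy
#' probabilities at every dose. For the Braun family the reported
#' probabilities are the *corrected* (true) marginals via
#' [braun_true_marginals()], since the model's `pi` parameters are not the
#' marginals when `psi1 != 0.5`; for the Gumbel and independence families
#' the logistic marginals are the marginals.
#'
#' @param draws A `posterior_draws` object from [sample_posterior()].
#' @param grid A [dose_grid()].
#' @return List with matrices `pi_T` and `pi_E` (retained draws x doses).
#' @export
posterior_dose_summaries <- function(draws, grid = dose_grid()) {
  stopifnot(inherits(draws, "posterior_draws"))
  d <- draws$draws
  if (nrow(d) == 0L) stop("no retained draws", call. = FALSE)
  x <- matrix(as.integer(grid) - 1, nrow = nrow(d), ncol = length(grid),
              byrow = TRUE)
  pi_T <- expit(d[, "beta0_T"] + d[, "beta1_T"] * x)
  pi_E <- expit(d[, "beta0_E"] + d[, "beta1_E"] * x + d[, "beta2_E"] * x^2)
  if (draws$family == "braun") {
    psi <- d[, "psi"]
    k <- 1 / ((1 - psi) * (1 - pi_T * pi_E) + psi * pi_T * pi_E)
    tT <- k * pi_T * ((1 - pi_E) * (1 - psi) + pi_E * psi)
    tE <- k * pi_E * ((1 - pi_T) * (1 - psi) + pi_T * psi)
    pi_T <- tT
    pi_E <- tE
  }
  colnames(pi_T) <- colnames(pi_E) <- paste0("dose", as.integer(grid))
  list(pi_T = pi_T, pi_E = pi_E)
}
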