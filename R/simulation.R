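#' Built-in simulation scenarios
#'
#' The five standard scenarios of true per-dose marginal probabilities of
#' toxicity and efficacy over a four-level dose grid, shipped as a CSV
#' fixture. Scenarios 1-3 have toxicity and efficacy increasing in dose
#' with the optimal dose ranging from level 1 to 4; in scenario 4 levels 3
#' and 4 are both acceptable but 3 is optimal; in scenario 5 all doses are
#' safe but none is efficacious enough and the correct decision is
#' futility termination.
#'
#' @return `data.frame` with columns `scenario`, `dose`, `pi_T`, `pi_E`.
#' @export
scenario_table <- function() {
  path <- system.file("extdata", "scenarios.csv", package = "efttrial",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Truth object for one scenario
#'
#' Attaches the derived true desirability `D(z)` per dose and the optimal
#' decision: the desirability-maximising dose among the truly acceptable
#' ones (true `pi_T` below the toxicity bound and true `pi_E` above the
#' efficacy bound), or futility when no dose qualifies.
#'
#' @param id Scenario id, 1-5.
#' @param criteria A [design_criteria()] used for the derived columns.
#' @return A `scenario_truth` list: `id`, `doses` (data.frame with `dose`,
#'   `pi_T`, `pi_E`, `D`), `optimal` (dose index or `NA`), `futility_optimal`.
#' @export
scenario_truth <- function(id, criteria = design_criteria()) {
  tab <- scenario_table()
  if (!id %in% unique(tab$scenario))
    stop("unknown scenario id: ", id, call. = FALSE)
  doses <- tab[tab$scenario == id, c("dose", "pi_T", "pi_E")]
  rownames(doses) <- NULL
  doses$D <- desirability(doses$pi_T, doses$pi_E, criteria)
  ok <- doses$pi_T < criteria$pibar_T & doses$pi_E > criteria$piunder_E
  optimal <- if (any(ok)) doses$dose[ok][which.max(doses$D[ok])] else NA_integer_
  structure(list(id = id, doses = doses, optimal = as.integer(optimal),
                 futility_optimal = !any(ok)),
            class = "scenario_truth")
}

#' Simulate correlated binary (toxicity, efficacy) outcomes at one dose
#'
#' Draws i.i.d. outcome pairs from the 2x2 joint table implied by the
#' scenario's true marginals at the given dose under the generating joint
#' model. Because the Braun model's `pi` parameters are not its realised
#' marginals, `braun_truth_mode = "match"` (default) first inverts the
#' Braun marginal map so the *realised* marginals equal the scenario table
#' at every `psi1`; `"raw"` uses the table values directly as copula
#' parameters.
#'
#' @param truth A [scenario_truth()] (or any list with a `doses`
#'   data.frame holding `dose`, `pi_T`, `pi_E`).
#' @param dose Dose index.
#' @param copula Generating [copula_spec()].
#' @param n Number of subjects.
#' @param braun_truth_mode `"match"` or `"raw"`.
#' @return `data.frame` with `n` rows and columns `y_T`, `y_E`.
#' @export
generate_outcomes <- function(truth, dose, copula, n,
                              braun_truth_mode = c("match", "raw")) {
  braun_truth_mode <- match.arg(braun_truth_mode)
  stopifnot(n >= 1)
  row <- truth$doses[truth$doses$dose == dose, ]
  if (nrow(row) != 1L) stop("dose not in scenario grid", call. = FALSE)
  pair <- c(row$pi_T, row$pi_E)
  if (copula$family == "braun" && braun_truth_mode == "match")
    pair <- invert_braun_marginals(pair[1], pair[2], copula$psi)
  tab <- joint_table(pair[1], pair[2], copula)
  cell <- sample.int(4L, size = n, replace = TRUE, prob = tab)
  data.frame(y_T = as.integer(cell <= 2L), y_E = as.integer(cell %% 2L == 1L))
}

#' Run one adaptive phase I-II trial
#'
#' Executes the five-step adaptive algorithm: the first cohort is treated
#' at the lowest dose; after each cohort the posterior over all accrued
#' data is refit, the acceptable set screened, and the next cohort treated
#' at the desirability-maximising acceptable dose under the no-skip
#' escalation rule; the trial stops for futility whenever no dose is
#' acceptable, and otherwise selects the desirability-maximising
#' acceptable dose once the maximum sample size is reached. Desirability
#' is evaluated at the posterior means of the per-dose marginals
#' (plug-in); set `desirability_rule = "posterior_mean_of_D"` to use the
#' posterior mean of D instead.
#'
#' @param truth A [scenario_truth()].
#' @param gen_copula Generating [copula_spec()].
#' @param fit_family Family of the fitted model: `"braun"`, `"gumbel"` or
#'   `"independence"`.
#' @param prior A [prior_spec()].
#' @param criteria A [design_criteria()].
#' @param cohort_size Subjects per cohort (default 3).
#' @param max_cohorts Maximum number of cohorts (default 15, i.e. 45
#'   subjects).
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed governing the whole trial (generation and all
#'   refits); identical seeds give identical trials.
#' @param braun_truth_mode Passed to [generate_outcomes()].
#' @param desirability_rule `"plugin"` or `"posterior_mean_of_D"`.
#' @return A `trial_record` list: accrued `data`, per-cohort `log`
#'   (data.frame with cohort, dose, acceptable set, D values), `status`
#'   (`"completed"` or `"futility"`), `selected` dose (`NA` on futility),
#'   `n_per_dose` tally and `seed`.
#' @export
run_trial <- function(truth, gen_copula, fit_family, prior = prior_spec(),
                      criteria = design_criteria(), cohort_size = 3L,
                      max_cohorts = 15L, mcmc = mcmc_config(), seed = NULL,
                      braun_truth_mode = c("match", "raw"),
                      desirability_rule = c("plugin",
                                            "posterior_mean_of_D")) {
  braun_truth_mode <- match.arg(braun_truth_mode)
  desirability_rule <- match.arg(desirability_rule)
  if (!is.null(seed)) set.seed(seed)
  grid <- dose_grid(nrow(truth$doses))
  doses <- integer(0); yT <- integer(0); yE <- integer(0)
  current <- 1L; highest <- 1L
  status <- "completed"; selected <- NA_integer_
  log_rows <- vector("list", max_cohorts)

  for (cohort in seq_len(max_cohorts)) {
    out <- generate_outcomes(truth, current, gen_copula, cohort_size,
                             braun_truth_mode)
    doses <- c(doses, rep(current, cohort_size))
    yT <- c(yT, out$y_T); yE <- c(yE, out$y_E)
    data <- trial_data(doses, yT, yE, grid)

    fit <- sample_posterior(data, fit_family, prior, mcmc)
    sums <- posterior_dose_summaries(fit, grid)
    acc <- acceptable_doses(sums, criteria)
    D <- if (desirability_rule == "plugin") {
      desirability(colMeans(sums$pi_T), colMeans(sums$pi_E), criteria)
    } else {
      colMeans(desirability(sums$pi_T, sums$pi_E, criteria))
    }
    log_rows[[cohort]] <- data.frame(
      cohort = cohort, dose = current,
      acceptable = paste(acc, collapse = ","),
      t(stats::setNames(D, paste0("D", seq_along(D)))))

    decision <- next_dose(acc, D, highest, final = cohort == max_cohorts)
    if (decision$action == "stop_futility") {
      status <- "futility"
      break
    } else if (decision$action == "select") {
      selected <- decision$dose
    } else {
      current <- decision$dose
      highest <- max(highest, current)
    }
  }

  n_per_dose <- tabulate(doses, nbins = length(grid))
  structure(list(data = trial_data(doses, yT, yE, grid),
                 log = do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                       logical(1))]),
                 status = status, selected = selected,
                 n_per_dose = n_per_dose, seed = seed,
                 scenario = truth$id, fit_family = fit_family,
                 gen_copula = gen_copula),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("Adaptive trial (scenario ", x$scenario, ", fit ", x$fit_family,
      "): ", x$status, sep = "")
  if (!is.na(x$selected)) cat(", selected dose ", x$selected, sep = "")
  cat("\nsubjects per dose:", x$n_per_dose, "\n")
  invisible(x)
}

#' Monte-Carlo operating characteristics of the adaptive design
#'
#' Replicates [run_trial()] over independent seeds and aggregates the
#' per-dose selection proportions, the futility-termination proportion and
#' the mean number of subjects treated per dose. The per-replicate seeds
#' are spawned deterministically from `base_seed`, so results are
#' reproducible and replicates are independent.
#'
#' @inheritParams run_trial
#' @param n_trials Number of simulated trials.
#' @param base_seed Root seed spawning the per-trial seeds.
#' @param ... Further arguments passed to [run_trial()].
#' @return An `oc_result` list: `selection` (named per-dose proportions),
#'   `futility`, `mean_subjects` per dose, `n_trials`, and the generating /
#'   fitted model metadata. `futility + sum(selection)` is exactly 1.
#' @export
operating_characteristics <- function(truth, gen_copula, fit_family,
                                      n_trials = 1000L, base_seed = 1L,
                                      prior = prior_spec(),
                                      criteria = design_criteria(),
                                      cohort_size = 3L, max_cohorts = 15L,
                                      mcmc = mcmc_config(), ...) {
  stopifnot(n_trials >= 1L)
  seeds <- spawn_seeds(base_seed, n_trials)
  K <- nrow(truth$doses)
  sel <- integer(K); fut <- 0L
  subj <- matrix(0, nrow = n_trials, ncol = K)
  for (i in seq_len(n_trials)) {
    tr <- run_trial(truth, gen_copula, fit_family, prior, criteria,
                    cohort_size, max_cohorts, mcmc, seed = seeds[i], ...)
    if (tr$status == "futility") fut <- fut + 1L
    else sel[tr$selected] <- sel[tr$selected] + 1L
    subj[i, ] <- tr$n_per_dose
  }
  structure(list(
    selection = stats::setNames(sel / n_trials, paste0("dose", seq_len(K))),
    futility = fut / n_trials,
    mean_subjects = stats::setNames(colMeans(subj),
                                    paste0("dose", seq_len(K))),
    n_trials = n_trials, base_seed = base_seed,
    scenario = truth$id, gen_copula = gen_copula, fit_family = fit_family,
    cohort_size = cohort_size, max_cohorts = max_cohorts,
    prior_preset = prior$preset),
    class = "oc_result")
}

#' @export
print.oc_result <- function(x, digits = 3, ...) {
  psi <- if (is.null(x$gen_copula$psi)) "" else
    paste0(" (psi = ", x$gen_copula$psi, ")")
  cat("Operating characteristics: scenario ", x$scenario, ", data ",
      x$gen_copula$family, psi, ", fitted ", x$fit_family, ", ",
      x$n_trials, " trials\n", sep = "")
  m <- rbind(`selection prob.` = c(Futility = x$futility, x$selection),
             `mean subjects` = c(Futility = NA, x$mean_subjects))
  print(round(m, digits), na.print = "")
  invisible(x)
}

# deterministic per-replicate seed spawning (kept below 2^31)
spawn_seeds <- function(base_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(base_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Correlation-estimability study under a fixed design
#'
#' How well can the copula association parameter be estimated at phase
#' I-II sample sizes? Each replicate simulates a fixed (non-adaptive)
#' study with `n_per_dose` subjects at every dose from the generating
#' copula, fits the *same* copula family by MCMC, and records the
#' posterior mean of the association parameter; the mean and standard
#' deviation of these posterior means across replicates are reported.
#'
#' @inheritParams run_trial
#' @param copula Generating (and fitted) [copula_spec()];
#'   `"independence"` is not meaningful here.
#' @param n_per_dose Subjects at each dose (default 11, i.e. 44 total on
#'   the four-dose grid).
#' @param n_reps Number of replicate datasets (default 1000).
#' @param base_seed Root seed.
#' @return A `corr_study` list with `mean`, `sd`, the per-replicate
#'   posterior means `psi_hat`, and metadata.
#' @export
correlation_study <- function(truth, copula, n_per_dose = 11L,
                              n_reps = 1000L, prior = prior_spec(),
                              mcmc = mcmc_config(), base_seed = 1L,
                              braun_truth_mode = c("match", "raw")) {
  braun_truth_mode <- match.arg(braun_truth_mode)
  if (copula$family == "independence")
    stop("the independence model has no association parameter", call. = FALSE)
  seeds <- spawn_seeds(base_seed, n_reps)
  grid <- dose_grid(nrow(truth$doses))
  psi_hat <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    doses <- rep(as.integer(grid), each = n_per_dose)
    out <- do.call(rbind, lapply(as.integer(grid), function(z)
      generate_outcomes(truth, z, copula, n_per_dose, braun_truth_mode)))
    data <- trial_data(doses, out$y_T, out$y_E, grid)
    fit <- sample_posterior(data, copula$family, prior, mcmc)
    psi_hat[r] <- mean(fit$draws[, "psi"])
  }
  structure(list(mean = mean(psi_hat), sd = stats::sd(psi_hat),
                 psi_hat = psi_hat, n_reps = n_reps,
                 n_per_dose = n_per_dose, scenario = truth$id,
                 copula = copula, base_seed = base_seed),
            class = "corr_study")
}

#' @export
print.corr_study <- function(x, ...) {
  cat("Correlation estimability: scenario ", x$scenario, ", ",
      x$copula$family, " psi = ", x$copula$psi, ", ", x$n_per_dose,
      " subjects/dose, ", x$n_reps, " replicates\n", sep = "")
  cat(sprintf("mean posterior mean: %.3f (sd %.3f)\n", x$mean, x$sd))
  invisible(x)
}

#' Sweep operating characteristics along one design axis
#'
#' Repeats [operating_characteristics()] varying a single experimental
#' axis: the maximum sample size (values are total subjects, converted to
#' cohorts of `cohort_size`) or the prior set (`"PS1"`-`"PS4"`).
#'
#' @inheritParams operating_characteristics
#' @param axis `"sample_size"` or `"prior_set"`.
#' @param values Axis values: e.g. `c(30, 45, 60, 75)` or
#'   `c("PS1","PS2","PS3","PS4")`.
#' @return Tidy `data.frame` in long format: one row per condition x
#'   outcome (futility and each dose) with the selection proportion and
#'   mean subjects, plus a `correct` column holding the
#'   correct-decision probability of the condition.
#' @export
sweep_experiment <- function(axis = c("sample_size", "prior_set"), values,
                             truth, gen_copula, fit_family,
                             n_trials = 1000L, base_seed = 1L,
                             prior = prior_spec(),
                             criteria = design_criteria(),
                             cohort_size = 3L, max_cohorts = 15L,
                             mcmc = mcmc_config(), ...) {
  axis <- match.arg(axis)
  rows <- lapply(values, function(v) {
    if (axis == "sample_size") {
      stopifnot(v %% cohort_size == 0)
      oc <- operating_characteristics(truth, gen_copula, fit_family,
                                      n_trials, base_seed, prior, criteria,
                                      cohort_size,
                                      max_cohorts = as.integer(v / cohort_size),
                                      mcmc, ...)
    } else {
      oc <- operating_characteristics(truth, gen_copula, fit_family,
                                      n_trials, base_seed,
                                      prior_spec(preset = v), criteria,
                                      cohort_size, max_cohorts, mcmc, ...)
    }
    correct <- if (truth$futility_optimal) oc$futility else
      unname(oc$selection[truth$optimal])
    data.frame(axis = axis, value = as.character(v),
               outcome = c("futility", names(oc$selection)),
               selection = c(oc$futility, unname(oc$selection)),
               mean_subjects = c(NA, unname(oc$mean_subjects)),
               correct = correct)
  })
  do.call(rbind, rows)
}
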