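#' Load and validate a run configuration
#'
#' Reads a JSON configuration file, fills the standard defaults for every
#' omitted field (cohorts of 3, 15 cohorts, trade-off bounds (0.5, 0.55),
#' `q = 2`, threshold 0.05, prior preset PS1, 5000/1000 MCMC), and
#' validates all fields before any computation. The returned object
#' carries a provenance record (config file MD5, seed, package version).
#'
#' @param path Path to a JSON config file, or `NULL` for an all-defaults
#'   configuration.
#' @return A validated `run_config` list with components `design`,
#'   `prior`, `mcmc`, `scenario`, `gen_copula`, `fit_family`, `n_trials`,
#'   `seed`, `out`, `provenance`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  get_or <- function(name, default) {
    if (is.null(raw[[name]])) default else raw[[name]]
  }
  dsgn <- get_or("design", list())
  dget <- function(name, default)
    if (is.null(dsgn[[name]])) default else dsgn[[name]]
  criteria <- design_criteria(
    pibar_T = dget("pibar_T", 0.5),
    piunder_E = dget("piunder_E", 0.55),
    pistar = unlist(dget("pistar", c(0.25, 0.60))),
    q = dget("q", 2),
    p_threshold = dget("p_threshold", 0.05))
  cohort_size <- dget("cohort_size", 3L)
  max_cohorts <- dget("max_cohorts", 15L)
  if (cohort_size < 1L || max_cohorts < 1L)
    stop("config field error: cohort_size and max_cohorts must be >= 1",
         call. = FALSE)

  pr <- get_or("prior", list(preset = "PS1"))
  if (is.character(pr)) pr <- list(preset = pr)
  prior <- do.call(prior_spec, pr)

  mc <- get_or("mcmc", list())
  mcmc <- do.call(mcmc_config, mc)

  scenario <- get_or("scenario", 1L)
  if (!scenario %in% 1:5)
    stop("config field error: unknown scenario id ", scenario, call. = FALSE)

  gc <- get_or("gen_copula", list(family = "braun", psi = 0.5))
  gen_copula <- copula_spec(gc$family, gc$psi)

  fit_family <- get_or("fit_family", "braun")
  if (!fit_family %in% c("braun", "gumbel", "independence"))
    stop("config field error: unknown fit_family ", fit_family,
         call. = FALSE)

  seed <- as.integer(get_or("seed", 1L))
  cfg <- list(
    design = c(criteria, list(cohort_size = as.integer(cohort_size),
                              max_cohorts = as.integer(max_cohorts))),
    criteria = criteria, prior = prior, mcmc = mcmc,
    scenario = as.integer(scenario), gen_copula = gen_copula,
    fit_family = fit_family,
    n_trials = as.integer(get_or("n_trials", 1000L)),
    braun_truth_mode = get_or("braun_truth_mode", "match"),
    seed = seed, out = get_or("out", NULL),
    provenance = list(
      config_md5 = if (is.null(path)) NA_character_ else
        unname(tools::md5sum(path)),
      seed = seed,
      package_version = as.character(utils::packageVersion("efttrial")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  structure(cfg, class = "run_config")
}

#' Write operating characteristics to CSV or JSON
#'
#' Round-trippable tidy output by default; `paper_layout = TRUE` emits the
#' two-row-per-model arrangement of the printed summary tables (selection
#' proportions rounded to 3 decimals on the first row, mean subjects on
#' the second, columns ordered Futility then doses 1..K).
#'
#' @param oc An `oc_result` from [operating_characteristics()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @param paper_layout Emit the printed-table arrangement (CSV only).
#' @return `path`, invisibly.
#' @export
write_oc_table <- function(oc, path, format = c("csv", "json"),
                           paper_layout = FALSE) {
  stopifnot(inherits(oc, "oc_result"))
  format <- match.arg(format)
  res <- tryCatch({
    if (format == "json") {
      plain <- unclass(oc)
      plain$gen_copula <- list(family = oc$gen_copula$family,
                               psi = oc$gen_copula$psi)
      jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else if (paper_layout) {
      m <- rbind(selection = round(c(oc$futility, unname(oc$selection)), 3),
                 mean_subjects = c(NA, round(unname(oc$mean_subjects), 3)))
      df <- data.frame(row = rownames(m), m, check.names = FALSE)
      names(df) <- c("row", "Futility", seq_along(oc$selection))
      utils::write.csv(df, path, row.names = FALSE, na = "")
    } else {
      df <- data.frame(outcome = c("futility", names(oc$selection)),
                       selection = c(oc$futility, unname(oc$selection)),
                       mean_subjects = c(NA, unname(oc$mean_subjects)))
      utils::write.csv(df, path, row.names = FALSE, na = "")
    }
    path
  }, error = function(e) {
    stop("failed to write '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Read back a tidy operating-characteristics CSV
#'
#' @param path File written by [write_oc_table()] (tidy CSV format).
#' @return `data.frame` with columns `outcome`, `selection`,
#'   `mean_subjects`.
#' @export
read_oc_table <- function(path) {
  utils::read.csv(path)
}
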