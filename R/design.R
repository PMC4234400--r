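#' Trade-off design criteria
#'
#' The constants driving the efficacy-toxicity trade-off design:
#' `pibar_T`, the maximum acceptable toxicity probability assuming 100%
#' efficacy; `piunder_E`, the minimum acceptable efficacy probability
#' assuming no toxicity; an optional equally-desirable pair `pistar` used
#' to calibrate the contour exponent `q` (see [solve_q()]); and the
#' posterior-probability threshold `p_threshold` of the acceptability
#' criterion. Defaults are the standard configuration: bounds (0.5, 0.55),
#' `pistar = (0.25, 0.60)` taken to correspond to `q = 2`, threshold 0.05.
#'
#' @param pibar_T Upper toxicity bound, in (0,1).
#' @param piunder_E Lower efficacy bound, in (0,1).
#' @param pistar Length-2 equally-desirable (toxicity, efficacy) pair.
#' @param q Contour exponent (> 0), or the string `"solve"` to calibrate it
#'   from `pistar` via [solve_q()].
#' @param p_threshold Posterior-probability cutoff in (0,1); a dose is
#'   acceptable when the joint posterior probability of meeting both
#'   bounds strictly exceeds it.
#' @return A `design_criteria` list.
#' @export
design_criteria <- function(pibar_T = 0.5, piunder_E = 0.55,
                            pistar = c(0.25, 0.60), q = 2,
                            p_threshold = 0.05) {
  stopifnot(pibar_T > 0, pibar_T < 1, piunder_E > 0, piunder_E < 1,
            p_threshold > 0, p_threshold < 1, length(pistar) == 2L)
  if (identical(q, "solve")) {
    q <- solve_q(pibar_T, piunder_E, pistar)
  } else if (!is.numeric(q) || length(q) != 1L || q <= 0) {
    stop("`q` must be a positive scalar or \"solve\"", call. = FALSE)
  }
  structure(list(pibar_T = pibar_T, piunder_E = piunder_E,
                 pistar = as.numeric(pistar), q = q,
                 p_threshold = p_threshold),
            class = "design_criteria")
}

#' Desirability index of a (toxicity, efficacy) probability pair
#'
#' \deqn{D = 1 - \left[\left(\frac{\pi_T}{\bar\pi_T}\right)^q +
#'   \left(\frac{1-\pi_E}{1-\underline\pi_E}\right)^q\right]^{1/q}}
#' One minus the q-norm of the scaled (toxicity, inefficacy) coordinates:
#' 1 at the ideal point (0, 1) regardless of `q`, 0 along the trade-off
#' contour through \eqn{(\bar\pi_T, 1)} and \eqn{(0, \underline\pi_E)},
#' strictly decreasing in toxicity and increasing in efficacy. Larger is
#' better.
#'
#' @param pi_T,pi_E Probability vectors (recycled together).
#' @param criteria A [design_criteria()].
#' @return Numeric vector of desirability values.
#' @export
desirability <- function(pi_T, pi_E, criteria = design_criteria()) {
  stopifnot(inherits(criteria, "design_criteria"))
  q <- criteria$q
  1 - ((pi_T / criteria$pibar_T)^q +
         ((1 - pi_E) / (1 - criteria$piunder_E))^q)^(1 / q)
}

#' Calibrate the contour exponent q from an equally-desirable pair
#'
#' Finds the `q` at which the desirability of `pistar` is exactly zero,
#' i.e. `pistar` lies on the same trade-off contour as
#' \eqn{(\bar\pi_T, 1)} and \eqn{(0, \underline\pi_E)}. Solved by
#' bracketing/bisection (via [stats::uniroot()]) on `log q` to tolerance
#' 1e-10. A root exists iff both scaled coordinates of `pistar` are
#' strictly inside (0, 1).
#'
#' @inheritParams design_criteria
#' @return The calibrated `q`.
#' @export
solve_q <- function(pibar_T, piunder_E, pistar) {
  a <- pistar[1] / pibar_T
  b <- (1 - pistar[2]) / (1 - piunder_E)
  if (a <= 0 || a >= 1 || b <= 0 || b >= 1)
    stop("no root: pistar must lie strictly between the anchor points ",
         "(both scaled coordinates in (0,1))", call. = FALSE)
  f <- function(logq) {
    q <- exp(logq)
    (a^q + b^q)^(1 / q) - 1
  }
  # f > 0 as q -> 0+ and f -> max(a,b) - 1 < 0 as q -> Inf
  stats::uniroot(f, lower = log(1e-6), upper = log(1e6), tol = 1e-12)$root |>
    exp()
}

#' Acceptable-dose screening from posterior draws
#'
#' A dose is acceptable when the fraction of joint posterior draws with
#' `pi_T(z) < pibar_T` *and* `pi_E(z) > piunder_E` strictly exceeds
#' `p_threshold`.
#'
#' @param summaries Per-dose posterior draws, as returned by
#'   [posterior_dose_summaries()] (list with matrices `pi_T`, `pi_E`).
#' @param criteria A [design_criteria()].
#' @return Integer vector of acceptable dose indices (possibly empty).
#' @export
acceptable_doses <- function(summaries, criteria = design_criteria()) {
  stopifnot(inherits(criteria, "design_criteria"))
  ok <- summaries$pi_T < criteria$pibar_T & summaries$pi_E > criteria$piunder_E
  if (is.null(dim(ok))) ok <- matrix(ok, nrow = 1L)
  frac <- colMeans(ok)
  which(frac > criteria$p_threshold)
}

#' Next-dose decision
#'
#' Implements the per-interim decision of the adaptive algorithm: stop for
#' futility when no dose is acceptable; otherwise treat the next cohort at
#' the acceptable dose maximising the desirability index, under the
#' no-skip restriction that escalation may not exceed one level above the
#' highest dose tried so far (de-escalation is unrestricted); at the final
#' interim, select the desirability-maximising acceptable dose outright.
#' Ties break to the lower dose. If every acceptable dose lies above the
#' escalation ceiling, the trial escalates one level toward it.
#'
#' @param acceptable Integer vector of acceptable doses.
#' @param desirabilities Numeric vector of D(z) over the full grid.
#' @param highest_tried Highest dose administered so far.
#' @param final Is this the end-of-trial selection (step 5)?
#' @return List with `action` (`"treat"`, `"select"` or `"stop_futility"`)
#'   and `dose` (`NA` for futility).
#' @export
next_dose <- function(acceptable, desirabilities, highest_tried,
                      final = FALSE) {
  if (length(acceptable) == 0L)
    return(list(action = "stop_futility", dose = NA_integer_))
  if (final) {
    best <- acceptable[which.max(desirabilities[acceptable])]
    return(list(action = "select", dose = as.integer(best)))
  }
  candidates <- acceptable[acceptable <= highest_tried + 1L]
  if (length(candidates) == 0L)  # all acceptable doses above the ceiling
    return(list(action = "treat", dose = as.integer(highest_tried + 1L)))
  best <- candidates[which.max(desirabilities[candidates])]
  list(action = "treat", dose = as.integer(best))
}
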