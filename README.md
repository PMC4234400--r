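# efttrial

Simulation framework for Bayesian **phase I–II dose-finding trials** that
jointly model a binary toxicity endpoint and a binary efficacy endpoint.

Classical phase I oncology designs escalate on toxicity alone to find the
maximum tolerated dose. Phase I–II trade-off designs instead model both
endpoints and steer dose assignment by an explicit efficacy/toxicity
trade-off. Doing so requires a *joint* probability model for the correlated
binary pair (Y_T, Y_E), usually built from marginal dose–response curves
plus a copula-type association structure — and the copula is a modelling
choice that can be wrong. `efttrial` is built for the methodological
question that follows: **how much do the operating characteristics of a
phase I–II trial suffer when the joint model is misspecified, and can the
association parameter even be estimated at phase I–II sample sizes?**

## The models

Marginal dose–response over dose indices z = 1, …, K (default K = 4):

    logit π_T(z) = β0T + β1T (z − 1)
    logit π_E(z) = β0E + β1E (z − 1) + β2E (z − 1)²

Three joint models for (Y_T, Y_E) at each dose:

* **Braun** (Arnold–Strauss exponential family):
  π(y_T, y_E) ∝ π_E^{y_E}(1−π_E)^{1−y_E} π_T^{y_T}(1−π_T)^{1−y_T}
  ψ₁^{y_T y_E}(1−ψ₁)^{1−y_T y_E}, ψ₁ ∈ (0,1). Here ψ₁/(1−ψ₁) is the
  odds ratio between the endpoints, ψ₁ = 0.5 is independence, and the π
  parameters are **not** the marginals unless ψ₁ = 0.5
  (`braun_true_marginals()` / `invert_braun_marginals()` handle the
  correction).
* **Gumbel–Morgenstern**: product cells perturbed by
  (−1)^{y_E+y_T} π_E(1−π_E)π_T(1−π_T) ψ₂, ψ₂ ∈ (−1,1); marginals are
  preserved exactly.
* **Independence**: the outer product.

Inference is by an adaptive Metropolis-within-Gibbs sampler (Rcpp) with
normal priors on intercepts/quadratic, Gamma priors on the positive
slopes, and flat priors on the association parameter. The adaptive design
follows the Thall–Cook trade-off algorithm: a dose is *acceptable* when
the joint posterior probability of π_T(z) < π̄_T and π_E(z) > π̲_E exceeds
a threshold p; among acceptable doses, cohorts are assigned (no skipping
upward) to maximise the desirability index

    D(z) = 1 − [ (π_T(z)/π̄_T)^q + ((1−π_E(z))/(1−π̲_E))^q ]^{1/q}

and the trial stops for futility whenever no dose is acceptable.

## Worked example

```r
library(efttrial)

st <- scenario_truth(1)        # true curves for scenario 1 + derived D(z)
st$doses
#>   dose pi_T pi_E     D
#> 1    1 0.05 0.38 -0.38
#> 2    2 0.12 0.55 -0.03
#> 3    3 0.27 0.71  0.16
#> 4    4 0.50 0.83 -0.07
```

Dose 3 has the largest desirability (0.16) among doses meeting the bounds
(π̄_T = 0.5, π̲_E = 0.55), so it is the optimal dose of this scenario. Run
one adaptive trial with Braun-generated data (ψ₁ = 0.7) analysed under the
(misspecified) independence model:

```r
tr <- run_trial(st, copula_spec("braun", 0.7), "independence", seed = 101)
tr
#> Adaptive trial (scenario 1, fit independence): completed, selected dose 3
#> subjects per dose: 3 3 27 12
```

The trial escalated without skipping, concentrated 27 of 45 subjects at
the optimal dose and selected it. How estimable is the Braun association
at this sample size? A small correlation-estimability study (11 subjects
per dose, matching-model fit):

```r
correlation_study(st, copula_spec("braun", 0.7), n_reps = 20, base_seed = 5)
#> Correlation estimability: scenario 1, braun psi = 0.7, 11 subjects/dose, 20 replicates
#> mean posterior mean: 0.658 (sd 0.155)
```

The posterior mean is biased toward the independence value 0.5 — with 44
subjects, binary data carry limited information about ψ₁ (and far less
about the Gumbel ψ₂), which is the mechanistic reason the independence
working model competes so well in the full simulations
(`operating_characteristics()`, `sweep_experiment()`).

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "efttrial.R", package = "efttrial"))')" \
  simulate-trials --scenario 1 --gen braun --psi 0.7 --fit independence \
  --n-trials 1000 --seed 7 --out oc.csv
```

Subcommands: `simulate-trials`, `correlation-study`, `sweep`,
`desirability-table`, `single-trial`; JSON configs via `--config`.

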