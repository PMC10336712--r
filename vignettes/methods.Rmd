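---
title: "Meta-epidemiological effect priors and their use in value-of-information analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-epidemiological effect priors and their use in value-of-information analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rteprior)
```

## The problem

When a new randomized trial is being designed or prioritized there is,
almost by definition, little or no direct evidence about the relative
treatment effect (RTE) it will estimate.  Value-of-information (VOI)
calculations, which put a monetary value on the uncertainty a trial would
resolve, need a prior for that effect; a flat prior badly overstates the
plausible range of effects and therefore overstates the value of research.
`rteprior` builds informative RTE priors empirically, from a table of
historical trial results spanning several disease areas, and carries the
resulting prior through to a worked expected-value-of-sample-information
(EVSI) analysis for a proposed trial.

The unit of analysis is a *trial result*: a summary effect `y_i` on the
log odds-ratio or log hazard-ratio scale with a known standard error
`se_i`, labelled by disease area and by whether the comparison was
active-vs-active or active-vs-inactive.  Log odds and log hazard ratios
are pooled in one column by default (the outcome type is retained so
users can subset).  The package-wide sign convention is that a negative
log effect favours the new treatment.

## The hierarchical model

The base model is a three-level normal hierarchy:

$$y_i \sim N(\theta_i, se_i^2), \qquad
  \theta_i \sim N(\mu_A, \tau_A^2), \qquad
  \mu_A \sim N(M, \eta^2), \qquad
  \tau_A^2 \sim \pi(\kappa, \nu),$$

where `A` indexes disease area.  Both the area means and the
between-study variances are exchangeable across areas, so sparse areas
borrow strength from the whole collection — including for their
heterogeneity, which a sparse area cannot estimate on its own.  Three
families are available for $\pi$: log-normal (`log(tau2) ~ N(kappa,
nu^2)`), gamma (shape `kappa`, scale `nu`), and half-normal.  The
covariate model (`model2`) replaces the study-effect mean with
$\mu_A + B X_i$, where $X_i = 1$ for active-vs-active comparisons and the
coefficient `B` is shared across areas.

Hyperpriors are deliberately vague: $M \sim N(0, 1000^2)$,
$\eta \sim U(0,5)$, $B \sim N(0,1000^2)$; log-normal
$\kappa \sim N(0,1000^2)$, $\nu \sim U(0,5)$; gamma
$\kappa \sim U(0,50)$, $\nu \sim U(0,50)$; half-normal
$\kappa \sim \text{half-}N(0,1000^2)$ truncated to $[0,100]$ and
$\nu \sim U(0,5)$.  On the log-ratio scale, where effects rarely exceed
a few units, these are effectively flat.

Two modelling points were genuinely open and were settled as follows.
First, the half-normal family statement is ambiguous about which
quantity the location governs; we read it as
$\tau_A^2 \sim N(\kappa, \nu^2)$ truncated to non-negative values, with
the truncated half-normal hyperprior on the location $\kappa$.  Second,
the gamma family is parameterized as (shape, scale), which is the
reading consistent with naming its two hyperparameters "shape" and
"scale".  Both choices are implemented identically in the synthetic-data
generator, the `log_posterior()` density, and the sampler, so they are
internally consistent whichever convention the original analysis used.

### Fitting and diagnostics

`rte_hier()` fits any of the six model variants by MCMC through JAGS.
The statistical contract is the joint density — exposed independently as
`log_posterior()` and verified in the tests against a hand-coded
summation and against deterministic grid quadrature on pinned toy
problems — not the sampling algorithm.  Full-scale settings are 3 chains
of 150,000 retained iterations after 50,000 burn-in
(`mcmc_settings("paper")`); development and simulation studies use
3 × 5,000 after 2,000 (`mcmc_settings("test")`), which on the package's
simulated datasets (a few hundred records, 4–9 areas) mixes well and
reproduces quadrature results to two decimals.  Fits are exactly
reproducible from one integer seed (chain `c` uses RNG seed
`seed + c`).

Convergence is summarized by a split-chain potential-scale-reduction
statistic computed for every monitored parameter; a fit whose largest
R-hat exceeds the threshold (default 1.05) raises a flag, not an
exception.  Model fit is summarized by the residual deviance
$\sum_i (y_i-\theta_i)^2/se_i^2$ (the additive `log(2*pi*se^2)` constant
is omitted; it cancels in comparisons) and by DIC with the deviance
focused at the study-effect level: `Dbar` is the posterior mean residual
deviance, `pD = Dbar - D(posterior mean theta)`, `DIC = Dbar + pD`.

Hierarchical sharing is undefined with a single area, so such fits are
refused unless the area-level hyperparameters are pinned through
`fixed=` (the mechanism also used by the quadrature oracles and
degenerate-case studies).

## Predictive priors

The prior for a future trial's true effect in a *represented* area is
the posterior predictive $\theta_{pred} \sim N(\mu_A, \tau_A^2)$,
sampled once per retained posterior draw; under the covariate model,
active-vs-active predictions add the `B` draw.  For a *new* area, three
levels of prediction are used per posterior draw:
$\mu_{pred} \sim N(M, \eta^2)$, $\tau^2_{pred} \sim \pi(\kappa, \nu)$,
then $\theta_{pred}$.  The new-area prior therefore inherits
between-area spread and hyperparameter uncertainty on top of within-area
heterogeneity, and its standard deviation typically exceeds every
represented area's.

Predictive samples are moment-matched to a normal summary (variance
denominator `n - 1`), which is how such priors are conventionally
reported and consumed.  95% intervals use `z = 1.96` — the printed
reporting convention, which the published intervals reproduce exactly —
while other levels use exact normal quantiles.  One draw per posterior
draw keeps the Monte-Carlo error of the summary estimable as
`sd/sqrt(n_draws)`.  `prior_table()` assembles the per-area rows plus
the new-area ("other/unknown") row, with the generating model recorded
per row, since a published table may mix base-model rows with
covariate-model rows for the dominant area.

## The synthetic-data generator

Because the historical dataset behind the motivating analysis is not
deposited, `simulate_trial_dataset()` generates datasets from exactly
the model above: it draws `mu_A`, `tau2_A` from the hyper-model, then
per-record effects and observed estimates, with `se_i` drawn
log-uniformly on [0.05, 0.5] — roughly trials of 60 to 6,000 events —
and independent of the effects, matching the known-standard-error
assumption.  Defaults (`M = -0.1`, `eta = 0.2`, gamma heterogeneity
with mean `tau2 = 0.1`, nine areas) represent a realistic collection:
new treatments slightly better on average, modest spread between areas,
moderate within-area heterogeneity.  One root seed fans out to per-area
substreams, so resizing one area leaves the others' records unchanged.
`make_fixture_suite()` adds a composition like the motivating dataset
(nine areas with one holding ~87% of records, two comparator types).

What the generator does *not* emulate: publication bias or small-study
effects, correlation between `se_i` and effect size, non-normal
within-study likelihoods, or drift over calendar time.  Passing
parameter-recovery tests on these datasets therefore shows the machinery
is correct under the model's own assumptions, not that the model is
adequate for any particular real collection of trials.

## From prior to decision model

`apply_log_effect_prior()` turns a normal log-effect prior into the
induced distribution of a treated-arm event parameter.  Two conventions
are offered and always logged: multiplying the baseline *probability* by
`exp(theta)` (the default; it reproduces the published case-study
summaries, e.g. a 22% median recurrence from N(-0.115, 0.241) applied to
25%), or multiplying the baseline *rate*, which is the natural reading
of a hazard ratio.  Medians and intervals come from closed-form
log-normal quantiles; samples are returned for distribution fitting.
Under the probability convention, mass above 1 is truncated with a
warning whenever it exceeds 0.1% of the prior.

Gamma fitting is by moment matching (`shape = m^2/v`, `rate = m/v`) with
a sample-based maximum-likelihood alternative.  Fitting the rate-scale
case-study distribution gives a shape near 16.7 — close to, but not
exactly, the published (17.3, 66.1); since the original fitting method
is unstated, the published pair is treated as an input to the EVSI
comparison rather than a derivation target.  `bayes_combine_normals()`
(precision weighting) and `linear_pool()` (mixture with user weights)
cover the two standard ways of combining an empirical prior with, say,
an elicited one.

## The EVSI case study

The decision model is the minimal three-state Markov cohort model of
high-grade non-muscle-invasive bladder cancer: recurrence-free,
recurrence, dead.  The control-arm annual recurrence probability is 25%
and treated as known (`rate = -log(0.75)`); recurrence carries a
disease-specific mortality rate `-log(0.79)/5` per year, higher costs
($17,727/yr vs $5,585/yr, each with a published SE) and a slightly lower
utility (0.96 vs 0.997); the experimental arm adds $147.18/yr while
failure-free.  Costs are drawn gamma and utilities beta, moment-matched
to their published means and SEs.  Conventions chosen here and exposed
as arguments: 1-year cycles; horizon to age 100 from entry at 68; state
membership counted at cycle starts with no half-cycle correction; no
background (non-disease) mortality, since the published input table
lists no life-table input (a `mortality_rate` override exists); both
arms share one PSA draw within an inner simulation, which reduces
Monte-Carlo variance without changing the expectation.

EVSI follows the published algorithm: 1,000 outer draws of the true
treatment-arm rate from its prior, each followed by a simulated trial
(616 patients, 1:1 allocation, 2.5 years mean follow-up, Poisson events
on 770 person-years) and an exact conjugate gamma update; 1,000 inner
draws of the posterior rate and PSA parameters per outer draw estimate
each arm's expected net benefit at $150,000/QALY.  EVSI is the mean
best posterior expected net benefit minus the best prior expected net
benefit (the prior term uses 100 × the inner size, since this one
baseline enters every estimate).  The outer-loop standard error is
reported; population scaling uses the discounted patient stream
`sum_t patients/yr / 1.03^t` over the 10-year information horizon, a
formula the result object states explicitly.

### Known limitation: the reconstruction gap

The companion model behind the published case study is not deposited,
and its cycle/horizon/mortality conventions had to be reconstructed.
Under the conventions above, the package's nested Monte Carlo gives a
per-person EVSI of roughly $78–86k for the noninformative gamma(1, 1)
prior and $9–11k for the empirical gamma(17.3, 66.1) prior (seed-to-seed
range at 1,000 × 1,000) — the published values are $44,230 and $24,109.
The qualitative findings reproduce robustly: the empirical prior yields
strictly lower EVSI at matched seeds, EVSI is bounded by EVPI and
increases with sample size.  The quantitative gap is structural: a
sensitivity sweep over the model horizon (5 years, 10 years, lifetime)
moves both values together and reproduces neither pair, so no
cycle/horizon convention recovers the published numbers, and the
difference most plausibly lies in how the companion model maps a
recurrence into lifetime QALY and cost consequences.  The tests assert
the published dollar values with their stated tolerance and currently
fail them, by design: the comparison is reported honestly rather than
calibrated away.

## Numerical and degenerate-case policy

- Out-of-support parameter points get `log_posterior = -Inf`, never an
  error, so samplers and optimizers can probe freely.
- Variance-family draws are non-negative by construction (truncation by
  inverse-CDF for the half-normal); a zero `tau2` is allowed in the
  generator (degenerate studies) but must be pinned strictly positive
  for fitting.
- R-hat on a constant chain is undefined and returns `NA` with a
  warning rather than a number.
- `filter_for_analysis()` warns (rather than silently succeeding) when
  the filters remove every record; an area with exactly the minimum
  count is kept, since the rule is "fewer than".
- Simulation problem sizes in the test suite — 20 recovery replicates of
  9 areas × 30 records at 3 × 2,000 retained draws, EVSI property checks
  at 120–200 outer simulations, quadrature toys with 6 records — were
  chosen as the smallest sizes at which the checked properties have
  comfortable Monte-Carlo margins.

## Session info

```{r}
sessionInfo()
```
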