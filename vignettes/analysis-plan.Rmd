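---
title: "The Bayesian analysis plan: models, priors, decisions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Bayesian analysis plan: models, priors, decisions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfdbayes)
```

vfdbayes implements a pre-specified Bayesian analysis plan for a two-arm
multicentre trial of lower versus higher PEEP in ventilated patients without
ARDS. This vignette is the package's own account of the science: the outcome
definitions, the models and their assumptions, how every prior is built from
its elicitation constraint, the decision rules, what the synthetic trial
generator does and does not emulate, and the numerical choices made where
the plan leaves room.

## The ventilator-free-days outcome

Ventilator-free days (VFD) at day 28 count the whole days a patient was
alive and free of invasive ventilation between randomization and day 28,
provided the unassisted period lasted at least 24 consecutive hours.
Patients who died by day 28, or who were still invasively ventilated at day
28, score zero. The result is an ordinal outcome on 0–28 with a large spike
at zero (deaths plus prolonged ventilation) and a mass of survivors near
20–27.

`compute_vfd()` fixes the conventions the verbal definition leaves open:

- **Day counting.** Days are half-open intervals $[k, k+1)$ on the study
  clock (origin at randomization). A day counts only when the patient is
  unassisted for its entirety, which makes the outcome an integer in 0–28
  and gives a patient extubated at time $t$ with no reintubation exactly
  $28 - \lceil t \rceil$ free days.
- **The 24-hour qualifier** applies to every unassisted window: windows
  shorter than 24 h contribute no free days.
- **Zero rule.** "Ventilated for more than 28 days" is read as *on the
  ventilator at the day-28 horizon*: a patient never liberated within the
  window scores zero even if a mid-course extubation lasted more than 24 h.
  This reading makes the zero rule and the mid-course-window rule
  consistent: interrupted unassisted windows (extubation followed by
  reintubation) contribute free days only for patients ultimately off the
  ventilator at day 28. Whether interrupted windows count at all is
  configurable (`count_interrupted`, default `TRUE`); the definition is
  silent on reintubation, so the choice is exposed rather than hidden.
- Death on or before day 28 always gives zero; death *after* day 28 bounds
  the last unassisted window but does not zero the count.

The unit tests check these conventions against a brute-force oracle that
discretizes the timeline in 15-minute steps, over terminal extubations on a
grid and assorted reintubation courses.

## The three outcome models

All three models share one structure: a fixed treatment effect
$\theta$ (lower vs higher PEEP), hospital random intercepts, and the
registry priors:

$$b_h = \tau z_h, \quad z_h \sim \mathrm{Normal}(0, 1), \quad
  \tau \sim \mathrm{Half\text{-}Normal}(0, 0.5),$$

with $\theta$ given one of the four elicited priors below. The non-centred
parameterization of $b_h$ keeps the sampler stable when $\tau$ is near
zero.

**VFD (primary outcome)** is modelled with a hierarchical cumulative
logistic (proportional-odds) regression over the full 29-level scale:

$$P(\mathrm{VFD}_i \ge k) = \mathrm{logit}^{-1}(\theta\,x_i + b_{h_i} -
\alpha_k), \qquad k = 1, \dots, 28,$$

where $x_i$ indicates lower PEEP and $\alpha_1 < \dots < \alpha_{28}$ are
ordered cut-points. $\theta > 0$ (common OR > 1) means higher cumulative
odds of more VFDs — benefit. The model assumes proportional effects across
the ordinal scale (one common OR shifts every cumulative category
probability). All 29 categories are kept by default; `collapse_breaks`
offers a coarser scale as a configuration option.

**28-day mortality** uses hierarchical logistic regression,
$\mathrm{logit}\,P(\text{death}_i) = a_0 + \theta x_i + b_{h_i}$, with
benefit when OR < 1. **Ventilation duration**, among 28-day survivors only,
uses a hierarchical linear model with residual SD $\sigma_{res}$; $\theta$
is the mean difference in days and benefit is MD < 0.

Nuisance parameters get deliberately wide priors so the registry prior
dominates inference on $\theta$: Normal(0, 5) on intercepts, ordered
Normal(0, 5) on the cut-points (each truncated above its predecessor), and
Half-Normal(0, 5) on $\sigma_{res}$. These were not stated in the plan; the
scale 5 is chosen to be an order of magnitude wider than any treatment
prior.

**Subgroup analyses** refit the mortality logistic model with a subgroup
main effect and a treatment-by-subgroup interaction $\gamma$, over the
seven prespecified dichotomizations (cardiac arrest, surgical admission,
primary respiratory failure, BMI > 30, PaO₂/FiO₂ ≤ 200, LIPS ≥ 4,
APACHE ≥ 86). The plan names no interaction prior; the default is a weakly
informative Normal(0, 1) on the log-OR scale, configurable per call.

### Sampling and diagnostics

Posterior draws come from JAGS (via `rjags`): 4 chains × 1000 warmup + 1000
draws by default, with 500 adaptation steps. Chains start from deterministic
but dispersed initial values (the treatment effect offset by up to ±1.5
prior SDs per chain; cut-points at clamped empirical cumulative logits) and
per-chain RNG seeds derived arithmetically from the call's seed, so a seed
pins the draws exactly. The ordinal and logistic likelihoods are passed to
JAGS as sufficient statistics (multinomial / binomial counts per
arm-by-hospital cell) — algebraically identical to the per-patient
likelihood and roughly an order of magnitude faster at trial scale.

Convergence is gated at split-$\hat R \le 1.01$ (computed in-package by
splitting each chain in half) and bulk ESS ≥ 400 for $\theta$, $\tau$, and
$\gamma$; a split-$\hat R$ above 1.01 raises a classed warning rather than
silently returning. Each model's unnormalized log posterior is also
implemented directly (`vfd_log_posterior()` and friends) in the exact
parameterization the sampler uses — including the sequentially truncated
cut-point densities — and the test suite requires it to match an
independently coded brute-force evaluation to 1e-8 on small fixtures. This
separates "the model is what we say it is" from "the sampler converged".

Missing data are handled by complete-case analysis per model (the plan's
stated primary approach): rows missing the model's outcome, arm, hospital,
or subgroup covariate are dropped with a reported count. Degenerate inputs
error early and specifically: a single observed VFD category, a single
mortality class, fewer than two survivors with durations in a represented
arm, a constant subgroup indicator, or an empty arm-by-subgroup cell (named
in the error).

## The prior registry

Every treatment-effect prior is Normal(μ, σ) on its effect scale, with σ
*solved* from the published constraint rather than transcribed:

| outcome | neutral | optimistic | pessimistic | survey |
|---|---|---|---|---|
| VFD (log-OR) | (0, 0.354) | (0.7, 1.335) | (−0.7, 1.335) | (0.127, 0.352) |
| mortality (log-OR) | (0, 0.354) | (−0.16, 0.305) | (0.7, 1.335) | (0, 0.0745) |
| duration (days) | (0, 1.020) | (−0.4, 0.763) | (0.4, 0.763) | (0, 0.765) |

- **Neutral:** 95% prior mass on OR ∈ [0.5, 2], i.e. σ = ln 2 / 1.96 ≈
  0.354 (printed 0.35); for duration, 95% mass on MD ∈ [−2, 2] days, σ ≈
  1.02. The constraint only works if Normal(a, b) is read as mean and
  *standard deviation* — the reading adopted throughout.
- **Optimistic / pessimistic:** centred on moderate benefit or harm with σ
  solved so the prior keeps a 30% probability of the opposite outcome:
  σ = |μ| / z₀.₇. For μ = 0.7 this gives 1.335, printed as 1.34; the
  registry keeps both values side by side (`sigma` vs `printed_sigma`,
  flagged by `matches_printed`) instead of silently preferring either. The
  optimistic mortality centre is printed as −0.16 although ln 0.84 =
  −0.174; the printed value is the registry default and the discrepancy is
  recorded in the row's note.
- **Survey:** built from an expert survey of 57 intensivists. The VFD prior
  converts the elicited standardized mean difference 0.07 (95% interval
  −0.31 to 0.45) to the log-OR scale with the logistic-distribution factor
  π/√3 — the factor that reproduces the printed centre 0.13 exactly — and
  scales the interval half-width by z₀.₉₇₅. The mortality prior converts
  the elicited ±3% risk difference at a 29% control risk to log-ORs via
  logit differences, then applies the same half-width rule, giving σ =
  0.0745 (printed 0.075). Asymmetric intervals are collapsed by half their
  full width — the only reading that reproduces the printed value; the
  exact-mass solution on the asymmetric interval differs by ~1.3e-4 and is
  cross-checked in the tests.

Two registry entries need a documented stance. First, the protocol's
summary table lists the survey VFD prior as Normal(0, 0.6) while its body
text derives Normal(0.13, 0.35) from the stated survey inputs; the package
defaults to the derivation because it is reproducible from stated inputs,
and carries the table value as the printed alternative
(`protocol_priors(vfd_survey = "printed")`). Second, the solved survey
duration SD 0.765 would round to 0.77, not the printed 0.76; the full
registry ships both. `inst/extdata/protocol.yaml` versions every printed
constant so deviations are diffable.

## Decision rules

For each outcome × prior cell, `summarize_outcome()` reports the posterior
median effect with an equal-tailed 95% credible interval (exponentiated to
the OR scale for VFD and mortality), the probability of benefit, the ROPE
mass, the severe-harm probability, and a classification:

1. **Superior** if P(benefit) ≥ 0.975. The gate is inclusive (the summary
   table's "≥ 97.5%" wins over the text's "exceed"), and the boundary is
   unit-tested. The secondary 95% gate is reported alongside.
2. **Practically equivalent** if the entire 95% CrI lies inside the ROPE.
   The plan says only that conclusions follow from "how much of the CrI
   falls outside/inside" the ROPE; full-containment is the strictest common
   rule, and the fraction of the CrI width inside the ROPE is also reported
   so any alternative rule can be applied post hoc.
3. **Severe-harm signal** if the posterior mass beyond the severe-harm OR
   (0.75 for VFD, 1.25 for mortality) reaches the same 0.975 gate — the
   plan gives the thresholds but no gate, so the superiority gate is reused
   symmetrically and the raw probability is always reported.
4. Otherwise **indeterminate**.

The ROPE is OR ∈ (0.9, 1.1), which the plan equates with −0.1 < log OR <
0.1; the literal ±0.1 is the default (ln 0.9 = −0.105 differs in the third
decimal) and `rope_log_literal = FALSE` switches to the exact logs. Neither
a ROPE nor a severe-harm threshold exists for ventilation duration:
requesting one is an error, not a silent invention, and duration summaries
carry `NA` in those fields. Credible intervals use R's default quantile
interpolation (type 7), documented and frozen by a test.

## The synthetic trial generator

Real patient-level data from the motivating trial are not public, so the
generator is the package's test bed: a 969-patient, 13-hospital trial whose
ground truth mirrors the analysis models *exactly*, making parameter
recovery a sharp test rather than an approximation.

Per patient: a hospital is assigned uniformly; each hospital has one
independent Normal(0, τ²) intercept per outcome channel (the plan specifies
random effects per model, nothing joint); allocation is balanced permuted
1:1. VFD is drawn from the proportional-odds shift of a fixed baseline pmf,
so empirical cumulative ORs converge to exp(θ_VFD) at every cut-point —
verified at n = 200,000. Deaths are then drawn from *within* the VFD = 0
cell with probability p(die)/p(VFD = 0), which reproduces the logistic
mortality model exactly whenever the zero cell is at least as large as the
death probability; survivors get a log-normal ventilation duration (median
4 days, log-SD 0.8 — the plan names no distribution; heavy right skew is
the clinically realistic choice and deliberately stresses the Gaussian
duration model) with the treatment effect added on the day scale. Subgroup
covariates are drawn from fixed, clinically plausible distributions.

Defaults are the study conditions: baseline mortality 0.42 (higher-PEEP
arm) with a true mortality OR of 0.84; mild heterogeneity τ = 0.25; a
baseline VFD pmf with 0.48 mass at zero (deaths plus survivors ventilated
past day 28) and a survivor peak at 20–27 days; and θ_VFD = −0.165,
calibrated once so the arms differ by 1.0 mean VFD day, matching the
motivating trial's 17.7 − 16.7 gap. One point cannot be matched: arm mean
VFDs of 16.7/17.7 are arithmetically incompatible with 38–42% mortality,
since 42% zeros cap the mean at 16.2 even if every survivor scored 28. The
generator therefore reproduces the mortality rates (which have their own
sharp test) and the between-arm gap, and accepts a lower absolute VFD level
(≈ 11) as the price of a realistic survivor distribution.

What the generator does **not** emulate: ventilation-course dynamics (VFD
is drawn directly, not via `compute_vfd()` on simulated courses), any
correlation between a survivor's duration and their VFD, informative
missingness (covariates may be missing in real data; generated outcomes
never are), non-proportional odds, or arm imbalance in covariates. Passing
recovery tests on this generator therefore shows the pipeline is correct
*under the plan's own assumptions*; it cannot show robustness to their
violation. One structural constraint matters when configuring extreme
scenarios: a configured death probability above the zero-VFD cell mass is
clamped (the `mortality_capped` attribute counts affected patients), which
attenuates very large configured mortality effects; with the default
calibration the distortion is under one percentage point, and tests that
need an exact large effect lower the baseline mortality instead.

## Validation strategy and problem sizes

The test suite separates concerns: analytic prior arithmetic is checked
against the printed protocol values and against root-finding oracles;
model definitions against brute-force log posteriors on 8-patient fixtures
(tolerance 1e-8, five random parameter points per model); the sampler
against closed-form anchors (a 2×2 contingency OR, a two-sample mean
difference, prior recovery under a flat likelihood for all 12 registry
priors, within 3 Monte-Carlo SEs); and the whole chain by parameter
recovery — 20 simulated 969-patient trials per outcome with known θ and
τ = 0.25, requiring the 95% CrI to cover truth at least 17 of 20 times.
Replicate fits use 2 chains × 300 draws (the coverage indicator, not the
CrI's third decimal, is what is being counted); single-fit checks use
larger runs. Bundle-level determinism is asserted by running the full
12-cell pipeline twice from one master seed and requiring identical
summaries.

## Known limitations

- The proportional-odds assumption is imposed, not tested; the package
  reports no proportionality diagnostics.
- The duration model is Gaussian while realistic durations are right-skewed;
  at trial scale the posterior for the mean difference is driven by the
  CLT, but small-sample tail behaviour inherits the misspecification (this
  is the plan's model, reproduced faithfully).
- Hospital effects are independent across outcome channels in both the
  generator and the models; a shared-frailty structure is out of scope.
- The decision rules are threshold-based summaries, not a decision-theoretic
  loss analysis; no Bayes factors are computed.
- The elicitation functions consume the survey's published numeric
  summaries; the survey instrument itself is not modelled.
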