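# vfdbayes

A Bayesian statistical-analysis-plan pipeline for two-arm multicentre
ventilation trials comparing a lower versus a higher PEEP (positive
end-expiratory pressure) strategy in invasively ventilated patients without
ARDS. The package implements, as tested and reusable code, the full analysis
plan of a Bayesian re-analysis of such a trial:

- **Prior elicitation.** Every treatment-effect prior is a Normal(μ, σ) on
  the log odds-ratio scale (ventilator-free days, 28-day mortality) or the
  mean-difference-in-days scale (ventilation duration), with σ solved from a
  stated constraint: 95% coverage of OR ∈ [0.5, 2] (neutral), a 30%
  opposite-tail probability (optimistic/pessimistic), or an expert-survey
  interval (survey priors, including the SMD → log-OR conversion by π/√3 and
  the risk-difference → log-OR conversion through logit differences).
  Between-hospital heterogeneity gets τ ~ Half-Normal(0, 0.5).
- **Hierarchical models.** For ventilator-free days (VFD, ordinal 0–28): a
  proportional-odds cumulative logistic model
  `P(VFD ≥ k) = logit⁻¹(θ·lower + b_h − α_k)`; for 28-day mortality: a
  hierarchical logistic model; for ventilation duration among survivors: a
  hierarchical linear model. Treatment is a fixed effect θ, hospitals are
  random intercepts `b_h ~ Normal(0, τ²)`. Sampling is MCMC via JAGS with
  split-R̂ / effective-sample-size diagnostics; seven prespecified
  treatment-by-subgroup interaction models are included.
- **Decision engine.** Posterior probability of benefit (P(OR > 1) for VFD,
  P(OR < 1) for mortality, P(MD < 0) for duration), equal-tailed 95% credible
  intervals, mass in the region of practical equivalence (ROPE,
  −0.1 < log OR < 0.1), and a superiority / practical-equivalence /
  severe-harm classification gated at a posterior probability of 0.975.
- **Synthetic trial generator.** A 969-patient, 13-hospital generator whose
  ground truth mirrors the three analysis models exactly, used for
  calibration, parameter-recovery, and end-to-end pipeline tests.

## Worked example

```r
library(vfdbayes)

# 1. The prior registry, rebuilt from its elicitation constraints
reg <- protocol_priors()
reg[reg$outcome == "mortality_28d",
    c("label", "mu", "sigma", "printed_mu", "printed_sigma", "matches_printed")]
#>   label          mu  sigma printed_mu printed_sigma matches_printed
#> 1 neutral      0    0.354        0            0.35  TRUE
#> 2 optimistic  -0.16 0.305       -0.16         0.3   TRUE
#> 3 pessimistic  0.7  1.33         0.7          1.34  FALSE
#> 4 survey       0    0.0745       0            0.075 TRUE
```

Each row holds the full-precision σ solved from the stated constraint next
to the protocol's printed value; `matches_printed` flags the one registry
entry whose printed rounding (1.34) differs from the solved value (1.335) —
surfaced, never overwritten.

```r
# 2. A synthetic trial with known ground truth (mortality OR 0.84)
trial <- simulate_trial(sim_config(seed = 2026))
empirical_summaries(trial)$by_arm
#>   arm             n deaths mortality mean_vfd median_vfd mean_duration_survivors
#> 1 lower_peep    484    174     0.360     10.3          0                    6.00
#> 2 higher_peep   485    182     0.375     11.3          9                    5.31

# 3. Fit the hierarchical mortality model under the neutral prior
fit <- fit_mortality_model(trial, registry_prior(reg, "mortality_28d", "neutral"),
                           seed = 2026)
tidy(fit, exponentiate = TRUE)
#>   term       estimate std.error conf.low conf.high
#> 1 a0           -0.518     0.118  -0.753     -0.291
#> 2 tau           0.210     0.116   0.0215     0.475
#> 3 odds_ratio    0.938    NA       0.734      1.20

# 4. The analysis plan's decision summary
summarize_outcome(fit)
#>   outcome       prior_label or_median or_cri_lo or_cri_hi p_benefit p_rope p_severe_harm classification
#> 1 mortality_28d neutral         0.938     0.734       1.2      0.69  0.517         0.011 indeterminate
```

Reading the output: under the neutral prior the posterior median mortality
odds ratio for lower PEEP is 0.94 (95% CrI 0.73–1.20); the probability of
benefit P(OR < 1) is 0.69 — well short of the 0.975 superiority gate — with
52% of the posterior inside the ROPE and a 1% severe-harm probability, so
this single simulated trial is classified `indeterminate`. (This run's true
OR is 0.84; one 969-patient trial rarely reaches the gate on its own.)

`run_full_analysis(run_config(seed = 1))` runs all 3 outcomes × 4 priors and
returns the 12-row decision-summary bundle plus a reproducibility manifest;
`render_report()` and `plot_prior_sensitivity()` tabulate and plot the
prior-sensitivity continuum. `autoplot()` works on fits and on the prior
registry.

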