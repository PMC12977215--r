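# Versioned registry of every analysis-plan constant, as printed in the
# protocol, so deviations are diffable. Normal(mu, sigma): sigma is a
# standard deviation. Effect scales: log odds ratio (vfd, mortality_28d),
# mean difference in days (duration).
priors:
  vfd:
    neutral:     {mu: 0.0,   sigma: 0.35}
    optimistic:  {mu: 0.7,   sigma: 1.34}
    pessimistic: {mu: -0.7,  sigma: 1.34}
    # printed registry value; the body-text derivation is Normal(0.13, 0.35)
    survey:      {mu: 0.0,   sigma: 0.6}
  mortality_28d:
    neutral:     {mu: 0.0,   sigma: 0.35}
    optimistic:  {mu: -0.16, sigma: 0.3}
    pessimistic: {mu: 0.7,   sigma: 1.34}
    survey:      {mu: 0.0,   sigma: 0.075}
  duration:
    neutral:     {mu: 0.0,   sigma: 1.02}
    optimistic:  {mu: -0.4,  sigma: 0.76}
    pessimistic: {mu: 0.4,   sigma: 0.76}
    survey:      {mu: 0.0,   sigma: 0.76}
heterogeneity:
  distribution: half_normal
  sigma: 0.5
decision_thresholds:
  rope_or_lo: 0.9
  rope_or_hi: 1.1
  # the protocol equates the ROPE with (-0.1, 0.1) on the log-OR scale
  rope_log_literal: true
  superiority_prob: 0.975
  report_also_at: 0.95
  severe_harm_or_vfd: 0.75
  severe_harm_or_mort: 1.25
subgroup_cutoffs:
  bmi: "> 30"
  pf_ratio: "<= 200"
  lips: ">= 4"
  apache: ">= 86"
  cardiac_arrest: "yes vs no"
  surgical_admission: "surgical vs non-surgical"
  primary_respiratory_failure: "primary respiratory failure vs others"
elicited_survey:
  n_respondents: 57
  vfd: {smd: 0.07, lo: -0.31, hi: 0.45}
  mortality_28d: {control_risk: 0.29, rd: 0.0, rd_lo: -0.03, rd_hi: 0.03}
  duration: {md: 0.0, lo: -1.0, hi: 2.0}
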