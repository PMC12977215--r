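# The decision engine converts posterior draws of the treatment effect into
# the analysis plan's probabilistic conclusions.

#' Decision thresholds of the analysis plan
#'
#' ROPE bounds, superiority gate, and severe-harm odds ratios. The ROPE is
#' OR in (0.9, 1.1); the protocol equates this with (-0.1, 0.1) on the
#' log-OR scale and that literal reading is the default (`rope_log_literal =
#' FALSE` uses the exact `log(0.9)`, `log(1.1)` instead — they differ in the
#' third decimal). Superiority requires posterior probability of benefit
#' >= 0.975 (the registry's `>=`, with boundary behaviour unit-tested); the
#' same gate is reused for the severe-harm signal. Neither a ROPE nor a
#' severe-harm threshold is defined for ventilation duration.
#'
#' @param rope_or_lo,rope_or_hi ROPE bounds on the OR scale.
#' @param superiority_prob Posterior-probability gate for superiority.
#' @param severe_harm_or_vfd OR below which lower PEEP severely harms VFDs.
#' @param severe_harm_or_mort OR above which lower PEEP severely harms
#'   mortality.
#' @param report_also_at Secondary probability threshold reported alongside.
#' @param rope_log_literal Use (-0.1, 0.1) on the log scale (default) rather
#'   than the exact logs of the OR bounds.
#' @return A list of class `decision_thresholds` with the log-scale ROPE in
#'   `rope_log`.
#' @export
decision_thresholds <- function(rope_or_lo = 0.9, rope_or_hi = 1.1,
                                superiority_prob = 0.975,
                                severe_harm_or_vfd = 0.75,
                                severe_harm_or_mort = 1.25,
                                report_also_at = 0.95,
                                rope_log_literal = TRUE) {
  stopifnot(rope_or_lo < 1, rope_or_hi > 1,
            superiority_prob > 0.5, superiority_prob < 1)
  rope_log <- if (rope_log_literal) {
    round(c(rope_or_lo - 1, rope_or_hi - 1), 10)  # 0.9/1.1 read as -/+0.1
  } else {
    c(log(rope_or_lo), log(rope_or_hi))
  }
  structure(list(rope_or_lo = rope_or_lo, rope_or_hi = rope_or_hi,
                 rope_log = rope_log, superiority_prob = superiority_prob,
                 severe_harm_or_vfd = severe_harm_or_vfd,
                 severe_harm_or_mort = severe_harm_or_mort,
                 report_also_at = report_also_at,
                 rope_log_literal = rope_log_literal),
            class = "decision_thresholds")
}

theta_draws <- function(x) {
  if (inherits(x, "peep_fit")) return(x$draws$theta)
  if (is.numeric(x)) return(as.numeric(x))
  abort("expected a `peep_fit` or a numeric vector of draws")
}

fit_outcome <- function(x, outcome) {
  if (!is.null(outcome)) return(arg_match0(outcome, outcome_levels()))
  if (inherits(x, "peep_fit")) return(x$outcome)
  abort("`outcome` must be supplied with raw draws")
}

#' Posterior tail probability
#'
#' Fraction of treatment-effect draws beyond a threshold in a given
#' direction, e.g. the probability of benefit P(OR > 1) for VFDs is
#' `tail_probability(fit, "greater", 0)`.
#'
#' @param x A `peep_fit` or numeric vector of effect draws.
#' @param direction `"greater"` or `"less"`.
#' @param threshold Threshold on the effect scale (default 0).
#' @return A probability.
#' @export
tail_probability <- function(x, direction = c("greater", "less"),
                             threshold = 0) {
  direction <- match.arg(direction)
  th <- theta_draws(x)
  if (length(th) == 0L) abort("no draws")
  if (direction == "greater") mean(th > threshold) else mean(th < threshold)
}

#' Posterior mass inside the region of practical equivalence
#'
#' Fraction of log-OR draws inside the ROPE. Not defined for the ventilation
#' duration outcome, for which the call errors.
#'
#' @param x A `peep_fit` (log-OR outcome) or numeric log-OR draws.
#' @param thresholds A [decision_thresholds()].
#' @param outcome Outcome name, required with raw draws.
#' @return A probability.
#' @export
rope_probability <- function(x, thresholds = decision_thresholds(),
                             outcome = NULL) {
  outcome <- fit_outcome(x, outcome)
  if (outcome == "duration") {
    abort("no ROPE is defined for ventilation duration",
          class = "vfdbayes_domain_error")
  }
  th <- theta_draws(x)
  mean(th > thresholds$rope_log[1] & th < thresholds$rope_log[2])
}

#' Equal-tailed credible interval
#'
#' Quantile interval at the given level, using the default interpolation rule
#' of [stats::quantile()] (type 7, linear interpolation; e.g. draws 1..1000
#' at level 0.95 give (25.975, 975.025)).
#'
#' @param x A `peep_fit` or numeric draws.
#' @param level Interval probability (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
credible_interval <- function(x, level = 0.95) {
  th <- theta_draws(x)
  if (length(th) == 0L) abort("no draws")
  a <- (1 - level) / 2
  out <- unname(quantile(th, c(a, 1 - a), type = 7))
  c(lower = out[1], upper = out[2])
}

benefit_direction <- function(outcome) {
  switch(outcome, vfd = "greater", mortality_28d = "less",
         duration = "less")
}

severe_harm_probability <- function(x, outcome = NULL,
                                    thresholds = decision_thresholds()) {
  outcome <- fit_outcome(x, outcome)
  if (outcome == "duration") {
    abort("no severe-harm threshold is defined for ventilation duration",
          class = "vfdbayes_domain_error")
  }
  if (outcome == "vfd") {
    tail_probability(x, "less", log(thresholds$severe_harm_or_vfd))
  } else {
    tail_probability(x, "greater", log(thresholds$severe_harm_or_mort))
  }
}

#' Classify a posterior treatment effect
#'
#' Applies the analysis plan's decision rules in a fixed order: `superior`
#' when the probability of benefit reaches the superiority gate (>= 0.975 by
#' default, boundary inclusive); otherwise `practically_equivalent` when the
#' full 95% credible interval lies inside the ROPE; otherwise
#' `severe_harm_signal` when the posterior mass beyond the severe-harm OR
#' reaches the same gate; otherwise `indeterminate`. For ventilation duration
#' only the superiority rule applies (requesting a ROPE or severe-harm
#' classification for it is an error upstream).
#'
#' @param p_benefit Posterior probability of benefit.
#' @param cri Log-scale 95% credible interval `c(lower, upper)` (log-OR
#'   outcomes; ignored for duration).
#' @param p_severe_harm Posterior severe-harm probability (log-OR outcomes).
#' @param outcome Outcome name.
#' @param thresholds A [decision_thresholds()].
#' @return One of `"superior"`, `"practically_equivalent"`,
#'   `"severe_harm_signal"`, `"indeterminate"`.
#' @export
classify_effect <- function(p_benefit, cri = NULL, p_severe_harm = NULL,
                            outcome, thresholds = decision_thresholds()) {
  outcome <- arg_match0(outcome, outcome_levels())
  if (p_benefit >= thresholds$superiority_prob) return("superior")
  if (outcome != "duration") {
    if (!is.null(cri) &&
        cri[1] > thresholds$rope_log[1] && cri[2] < thresholds$rope_log[2]) {
      return("practically_equivalent")
    }
    if (!is.null(p_severe_harm) &&
        p_severe_harm >= thresholds$superiority_prob) {
      return("severe_harm_signal")
    }
  }
  "indeterminate"
}

#' Summarize a fitted outcome model into a decision row
#'
#' Assembles the full decision summary for one outcome-by-prior cell:
#' posterior median and 95% CrI on the effect scale (and exponentiated to the
#' OR scale for VFD and mortality), probability of benefit (with the
#' secondary 95%-gate report), ROPE mass, severe-harm probability, the
#' fraction of the CrI width inside the ROPE, and the classification. ROPE
#' and severe-harm fields are `NA` for ventilation duration, for which they
#' are not defined.
#'
#' @param fit A `peep_fit`.
#' @param thresholds A [decision_thresholds()].
#' @param level Credible-interval level (default 0.95).
#' @return A one-row tibble (a `DecisionSummary`).
#' @export
summarize_outcome <- function(fit, thresholds = decision_thresholds(),
                              level = 0.95) {
  stopifnot(inherits(fit, "peep_fit"))
  outcome <- fit$outcome
  th <- theta_draws(fit)
  cri <- credible_interval(fit, level)
  med <- median(th)
  p_benefit <- tail_probability(fit, benefit_direction(outcome), 0)
  log_or_scale <- outcome != "duration"
  if (log_or_scale) {
    p_rope <- rope_probability(fit, thresholds)
    p_harm <- severe_harm_probability(fit, thresholds = thresholds)
    width <- cri[2] - cri[1]
    overlap <- max(0, min(cri[2], thresholds$rope_log[2]) -
                     max(cri[1], thresholds$rope_log[1]))
    inside_frac <- if (width > 0) overlap / width else {
      as.numeric(med > thresholds$rope_log[1] & med < thresholds$rope_log[2])
    }
  } else {
    p_rope <- NA_real_
    p_harm <- NA_real_
    inside_frac <- NA_real_
  }
  tibble(
    outcome = outcome,
    prior_label = fit$prior$label,
    effect_scale = fit$prior$effect_scale,
    posterior_median = med,
    cri_lo = unname(cri[1]),
    cri_hi = unname(cri[2]),
    or_median = if (log_or_scale) exp(med) else NA_real_,
    or_cri_lo = if (log_or_scale) exp(cri[[1]]) else NA_real_,
    or_cri_hi = if (log_or_scale) exp(cri[[2]]) else NA_real_,
    p_benefit = p_benefit,
    superior_at_95 = p_benefit >= thresholds$report_also_at,
    p_rope = p_rope,
    p_severe_harm = p_harm,
    cri_inside_rope_fraction = inside_frac,
    classification = classify_effect(
      p_benefit, cri = if (log_or_scale) cri else NULL,
      p_severe_harm = if (log_or_scale) p_harm else NULL,
      outcome = outcome, thresholds = thresholds),
    converged = fit$converged,
    n = fit$n_obs,
    seed = fit$seed
  )
}
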