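#' Wrap raw effect draws as a fit object
#'
#' Builds a minimal `peep_fit` from a numeric vector of treatment-effect
#' draws, so the decision engine (e.g. [summarize_outcome()]) can be applied
#' to analytically constructed or externally produced draws.
#'
#' @param theta Numeric draws of the treatment effect.
#' @param outcome Outcome name.
#' @param label Prior label to record (default `"external"`).
#' @param tau Optional draws of the between-hospital SD.
#' @return A `peep_fit`.
#' @export
peep_fit_from_draws <- function(theta, outcome, label = "external",
                                tau = NULL) {
  outcome <- arg_match0(outcome, outcome_levels())
  structure(
    list(outcome = outcome,
         draws = tibble(.chain = 1L, .iteration = seq_along(theta),
                        theta = as.numeric(theta),
                        tau = if (is.null(tau)) NA_real_ else as.numeric(tau)),
         prior = prior_spec(outcome, label, 0, 1),
         tau_prior = heterogeneity_prior(),
         seed = NA_integer_, n_obs = NA_integer_, n_dropped = 0L,
         diagnostics = tibble(param = character(), rhat = numeric(),
                              ess = numeric()),
         converged = NA),
    class = "peep_fit")
}

#' Tidy a fitted model
#'
#' One row per monitored parameter with the posterior median, SD, and
#' equal-tailed credible interval, in broom's column conventions.
#'
#' @param x A `peep_fit`.
#' @param conf.level Credible level (default 0.95).
#' @param exponentiate Exponentiate the treatment effect to the OR scale
#'   (log-OR outcomes only).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy peep_fit
#' @export
tidy.peep_fit <- function(x, conf.level = 0.95, exponentiate = FALSE, ...) {
  params <- setdiff(names(x$draws), c(".chain", ".iteration"))
  out <- purrr::map(params, function(p) {
    v <- x$draws[[p]]
    ci <- quantile(v, c((1 - conf.level) / 2, 1 - (1 - conf.level) / 2),
                   na.rm = TRUE)
    tibble(term = p, estimate = median(v), std.error = sd(v),
           conf.low = unname(ci[1]), conf.high = unname(ci[2]))
  }) %>% list_rbind()
  if (exponentiate) {
    if (x$outcome == "duration") {
      abort("cannot exponentiate a mean difference in days",
            class = "vfdbayes_domain_error")
    }
    i <- out$term == "theta"
    out[i, c("estimate", "conf.low", "conf.high")] <-
      exp(out[i, c("estimate", "conf.low", "conf.high")])
    out$std.error[i] <- NA_real_
    out$term[i] <- "odds_ratio"
  }
  out
}

#' Glance at a fitted model
#'
#' @param x A `peep_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample size, sampler dimensions, and the
#'   worst convergence diagnostics over the key parameters.
#' @method glance peep_fit
#' @export
glance.peep_fit <- function(x, ...) {
  key <- x$diagnostics[x$diagnostics$param %in% c("theta", "tau", "gamma"), ]
  tibble(outcome = x$outcome,
         prior_label = x$prior$label,
         n = x$n_obs,
         n_dropped = x$n_dropped,
         n_chains = length(unique(x$draws$.chain)),
         n_draws = nrow(x$draws),
         max_rhat = if (nrow(key)) max(key$rhat) else NA_real_,
         min_ess = if (nrow(key)) min(key$ess) else NA_real_,
         converged = x$converged,
         seed = x$seed)
}

#' Plot the posterior of the treatment effect
#'
#' Density of the treatment-effect draws on the effect scale, with the null
#' value, the 95% credible interval, and (for log-OR outcomes) the ROPE.
#'
#' @param object A `peep_fit`.
#' @param thresholds A [decision_thresholds()] (for the ROPE band).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peep_fit
#' @export
autoplot.peep_fit <- function(object, thresholds = decision_thresholds(),
                              ...) {
  ci <- credible_interval(object)
  df <- tibble(theta = object$draws$theta)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey30")
  if (object$outcome != "duration") {
    gg <- gg + ggplot2::annotate("rect", xmin = thresholds$rope_log[1],
                                 xmax = thresholds$rope_log[2],
                                 ymin = -Inf, ymax = Inf, alpha = 0.15,
                                 fill = "steelblue")
  }
  gg +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = unname(ci), colour = "firebrick") +
    ggplot2::labs(
      x = if (object$outcome == "duration") {
        "mean difference (days)"
      } else {
        "log odds ratio"
      },
      y = "posterior density",
      title = sprintf("%s | %s prior", object$outcome, object$prior$label)) +
    ggplot2::theme_minimal()
}
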