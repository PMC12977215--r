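# Unnormalized log posterior densities of the three hierarchical models, in
# the exact parameterization the sampler uses: non-centred hospital effects
# (b_h = tau * z_h with z_h standard normal), Half-Normal tau, ordered
# cut-points with sequentially truncated Normal(0, 5) densities. These
# functions define the models independently of JAGS and are the contract the
# test suite checks against brute-force evaluation; they match the sampled
# posterior up to the additive constant of the sufficient-statistic
# (multinomial/binomial coefficient) terms.

log_halfnormal <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) + dnorm(x, 0, scale, log = TRUE))
}

log_prior_common <- function(theta, tau, z, prior, tau_prior) {
  dnorm(theta, prior$mu, prior$sigma, log = TRUE) +
    log_halfnormal(tau, tau_prior$sigma) +
    sum(dnorm(z, 0, 1, log = TRUE))
}

# ordered cut-points: alpha_1 ~ N(0, s); alpha_k | alpha_{k-1} ~ N(0, s)
# truncated to (alpha_{k-1}, Inf)
log_prior_cutpoints <- function(alpha, s = NUISANCE_SD) {
  if (is.unsorted(alpha, strictly = TRUE)) return(-Inf)
  k <- length(alpha)
  dnorm(alpha[1], 0, s, log = TRUE) +
    sum(dnorm(alpha[-1], 0, s, log = TRUE) -
          pnorm(alpha[-k], 0, s, lower.tail = FALSE, log.p = TRUE))
}

vfd_category_logprob <- function(eta, alpha, y1) {
  # y1 in 1..K (VFD + 1); P(Y >= k) = plogis(eta - alpha[k-1])
  q <- plogis(outer(eta, alpha, `-`))            # n x K-1
  K <- length(alpha) + 1L
  p <- cbind(1 - q[, 1L], q[, -ncol(q), drop = FALSE] - q[, -1L, drop = FALSE],
             q[, ncol(q)])
  log(p[cbind(seq_along(eta), y1)])
}

#' Unnormalized log posterior of the VFD model
#'
#' Evaluates the hierarchical cumulative logistic model's log posterior (up
#' to an additive constant) at a given parameter point, using the same
#' parameterization as [fit_vfd_model()]: treatment effect `theta`,
#' between-hospital SD `tau`, standardized hospital effects `z` (so
#' `b_h = tau * z_h`), and strictly increasing cut-points `alpha` (length 28
#' for the full 0..28 scale).
#'
#' @param data Patient table with `arm`, `hospital_id`, `vfd`.
#' @param theta,tau,z,alpha Parameter point.
#' @param prior,tau_prior Treatment and heterogeneity priors.
#' @return Scalar log density (`-Inf` outside the support).
#' @export
vfd_log_posterior <- function(data, theta, tau, z, alpha, prior,
                              tau_prior = heterogeneity_prior()) {
  lp <- log_prior_common(theta, tau, z, prior, tau_prior) +
    log_prior_cutpoints(alpha)
  if (!is.finite(lp)) return(-Inf)
  x <- as.integer(as.character(data$arm) == "lower_peep")
  eta <- theta * x + tau * z[data$hospital_id]
  lp + sum(vfd_category_logprob(eta, alpha, as.integer(data$vfd) + 1L))
}

#' Unnormalized log posterior of the 28-day mortality model
#'
#' @inheritParams vfd_log_posterior
#' @param a0 Intercept (log odds of death in the higher-PEEP arm at the
#'   average hospital).
#' @return Scalar log density.
#' @export
mortality_log_posterior <- function(data, theta, tau, z, a0, prior,
                                    tau_prior = heterogeneity_prior()) {
  lp <- log_prior_common(theta, tau, z, prior, tau_prior) +
    dnorm(a0, 0, NUISANCE_SD, log = TRUE)
  if (!is.finite(lp)) return(-Inf)
  x <- as.integer(as.character(data$arm) == "lower_peep")
  eta <- a0 + theta * x + tau * z[data$hospital_id]
  y <- as.integer(data$died_by_day28)
  lp + sum(y * stats::plogis(eta, log.p = TRUE) +
             (1 - y) * stats::plogis(-eta, log.p = TRUE))
}

#' Unnormalized log posterior of the ventilation-duration model
#'
#' Evaluated over 28-day survivors with a recorded duration only.
#'
#' @inheritParams mortality_log_posterior
#' @param sigma_res Residual SD (days), Half-Normal(0, 5) prior.
#' @return Scalar log density.
#' @export
duration_log_posterior <- function(data, theta, tau, z, a0, sigma_res, prior,
                                   tau_prior = heterogeneity_prior()) {
  lp <- log_prior_common(theta, tau, z, prior, tau_prior) +
    dnorm(a0, 0, NUISANCE_SD, log = TRUE) +
    log_halfnormal(sigma_res, NUISANCE_SD)
  if (!is.finite(lp) || sigma_res <= 0) return(-Inf)
  d <- data[data$died_by_day28 %in% FALSE & !is.na(data$vent_duration_days), ]
  x <- as.integer(as.character(d$arm) == "lower_peep")
  mu <- a0 + theta * x + tau * z[d$hospital_id]
  lp + sum(dnorm(d$vent_duration_days, mu, sigma_res, log = TRUE))
}

#' Unnormalized log posterior of the subgroup-interaction mortality model
#'
#' @inheritParams mortality_log_posterior
#' @param covariate Subgroup covariate (see [subgroup_indicator()]).
#' @param beta Subgroup main effect (Normal(0, 5) prior).
#' @param gamma Treatment-by-subgroup interaction.
#' @param interaction_prior Prior for `gamma`.
#' @return Scalar log density.
#' @export
subgroup_log_posterior <- function(data, covariate, theta, tau, z, a0, beta,
                                   gamma, prior, interaction_prior,
                                   tau_prior = heterogeneity_prior()) {
  lp <- log_prior_common(theta, tau, z, prior, tau_prior) +
    dnorm(a0, 0, NUISANCE_SD, log = TRUE) +
    dnorm(beta, 0, NUISANCE_SD, log = TRUE) +
    dnorm(gamma, interaction_prior$mu, interaction_prior$sigma, log = TRUE)
  if (!is.finite(lp)) return(-Inf)
  s <- as.integer(subgroup_indicator(data, covariate))
  x <- as.integer(as.character(data$arm) == "lower_peep")
  eta <- a0 + theta * x + beta * s + gamma * x * s +
    tau * z[data$hospital_id]
  y <- as.integer(data$died_by_day28)
  lp + sum(y * stats::plogis(eta, log.p = TRUE) +
             (1 - y) * stats::plogis(-eta, log.p = TRUE))
}
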