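# Independent brute-force oracles. These are deliberately naive (time grids,
# per-patient loops, root finding on the Normal CDF) and share no code with
# the package implementations they check.

# Ventilator-free days by discretizing the timeline in 15-minute steps.
# Episode endpoints in the tests are multiples of 0.25 days, so the grid is
# exact. A day counts when all its steps are unassisted, its maximal
# unassisted run is >= 24h, and the patient is alive past the horizon and off
# the ventilator at it.
oracle_vfd <- function(episodes, death_day = NA, horizon = 28) {
  dt <- 1 / 96
  end_obs <- if (is.na(death_day)) horizon + 3 else death_day
  if (!is.na(death_day) && death_day <= horizon) return(0L)
  grid <- seq(0, end_obs - dt, by = dt)
  assisted <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(episodes))) {
    assisted <- assisted |
      (grid >= episodes$start[i] & grid < episodes$end[i])
  }
  # still on the ventilator at the horizon?
  at_h <- which.min(abs(grid - (horizon - dt)))
  if (assisted[at_h]) return(0L)
  runs <- rle(assisted)
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  run_len <- (runs$lengths * dt)[run_id]
  free <- 0L
  for (k in 0:(horizon - 1)) {
    in_day <- grid >= k & grid < k + 1
    if (!any(assisted[in_day]) && all(run_len[in_day] >= 1) &&
        sum(in_day) == 96) {
      free <- free + 1L
    }
  }
  free
}

# Brute-force unnormalized log posteriors, written as per-patient loops.
oracle_lp_common <- function(theta, tau, z, prior, tau_prior) {
  if (tau < 0) return(-Inf)
  lp <- dnorm(theta, prior$mu, prior$sigma, log = TRUE)
  lp <- lp + log(2) + dnorm(tau, 0, tau_prior$sigma, log = TRUE)
  for (zz in z) lp <- lp + dnorm(zz, 0, 1, log = TRUE)
  lp
}

oracle_lp_vfd <- function(data, theta, tau, z, alpha, prior, tau_prior) {
  lp <- oracle_lp_common(theta, tau, z, prior, tau_prior)
  if (any(diff(alpha) <= 0)) return(-Inf)
  lp <- lp + dnorm(alpha[1], 0, 5, log = TRUE)
  for (k in 2:length(alpha)) {
    lp <- lp + dnorm(alpha[k], 0, 5, log = TRUE) -
      log(1 - pnorm(alpha[k - 1], 0, 5))
  }
  K <- length(alpha) + 1
  for (i in seq_len(nrow(data))) {
    eta <- theta * (data$arm[i] == "lower_peep") +
      tau * z[data$hospital_id[i]]
    k <- data$vfd[i] + 1
    cum_ge <- function(j) {
      if (j <= 1) 1 else if (j > K - 1 + 1) 0 else 1 / (1 + exp(-(eta - alpha[j - 1])))
    }
    p_k <- cum_ge(k) - cum_ge(k + 1)
    lp <- lp + log(p_k)
  }
  lp
}

oracle_lp_mortality <- function(data, theta, tau, z, a0, prior, tau_prior) {
  lp <- oracle_lp_common(theta, tau, z, prior, tau_prior) +
    dnorm(a0, 0, 5, log = TRUE)
  for (i in seq_len(nrow(data))) {
    eta <- a0 + theta * (data$arm[i] == "lower_peep") +
      tau * z[data$hospital_id[i]]
    p <- 1 / (1 + exp(-eta))
    lp <- lp + log(if (data$died_by_day28[i]) p else 1 - p)
  }
  lp
}

oracle_lp_duration <- function(data, theta, tau, z, a0, sigma_res, prior,
                               tau_prior) {
  if (sigma_res <= 0) return(-Inf)
  lp <- oracle_lp_common(theta, tau, z, prior, tau_prior) +
    dnorm(a0, 0, 5, log = TRUE) +
    log(2) + dnorm(sigma_res, 0, 5, log = TRUE)
  for (i in seq_len(nrow(data))) {
    if (data$died_by_day28[i] || is.na(data$vent_duration_days[i])) next
    mu <- a0 + theta * (data$arm[i] == "lower_peep") +
      tau * z[data$hospital_id[i]]
    lp <- lp + dnorm(data$vent_duration_days[i], mu, sigma_res, log = TRUE)
  }
  lp
}

oracle_lp_subgroup <- function(data, s, theta, tau, z, a0, beta, gamma,
                               prior, int_prior, tau_prior) {
  lp <- oracle_lp_common(theta, tau, z, prior, tau_prior) +
    dnorm(a0, 0, 5, log = TRUE) + dnorm(beta, 0, 5, log = TRUE) +
    dnorm(gamma, int_prior$mu, int_prior$sigma, log = TRUE)
  for (i in seq_len(nrow(data))) {
    x <- as.integer(data$arm[i] == "lower_peep")
    eta <- a0 + theta * x + beta * s[i] + gamma * x * s[i] +
      tau * z[data$hospital_id[i]]
    p <- 1 / (1 + exp(-eta))
    lp <- lp + log(if (data$died_by_day28[i]) p else 1 - p)
  }
  lp
}

# Root-finding oracle: the SD at which Normal(mu, sd) puts `tail` mass on the
# other side of zero.
oracle_opposite_tail_sd <- function(mu, tail) {
  f <- if (mu > 0) {
    function(s) pnorm(0, mu, s) - tail
  } else {
    function(s) (1 - pnorm(0, mu, s)) - tail
  }
  uniroot(f, c(1e-6, 100), tol = 1e-12)$root
}

# Boundary-sigma oracle: sigma at which a centred Normal places exactly
# `mass` on the (possibly asymmetric) interval (lo, hi).
oracle_interval_mass_sd <- function(lo, hi, mass) {
  uniroot(function(s) pnorm(hi, 0, s) - pnorm(lo, 0, s) - mass,
          c(1e-6, 100), tol = 1e-12)$root
}

# 2x2 contingency odds ratio (lower vs higher PEEP)
oracle_contingency_or <- function(data) {
  tab <- table(data$arm, data$died_by_day28)
  (tab["lower_peep", "TRUE"] / tab["lower_peep", "FALSE"]) /
    (tab["higher_peep", "TRUE"] / tab["higher_peep", "FALSE"])
}
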