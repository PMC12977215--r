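test_that("model log posteriors match brute-force evaluation", {
  d <- tiny_trial()
  reg <- protocol_priors()
  pv <- registry_prior(reg, "vfd", "neutral")
  pm <- registry_prior(reg, "mortality_28d", "optimistic")
  pd <- registry_prior(reg, "duration", "pessimistic")
  pint <- prior_spec("mortality_28d", "interaction", 0, 1)
  tp <- heterogeneity_prior(0.5)
  d$bmi <- c(32, 25, 31, 22, 35, 28, 24, 33)
  s <- as.integer(subgroup_indicator(d, "bmi"))

  set.seed(99)
  for (point in 1:5) {
    theta <- rnorm(1, 0, 0.5)
    tau <- abs(rnorm(1, 0, 0.3))
    z <- rnorm(2)
    alpha <- sort(rnorm(28, 0, 2))
    a0 <- rnorm(1)
    sigma_res <- abs(rnorm(1, 1, 0.5)) + 0.2
    beta <- rnorm(1, 0, 0.5)
    gam <- rnorm(1, 0, 0.5)

    expect_equal(vfd_log_posterior(d, theta, tau, z, alpha, pv, tp),
                 oracle_lp_vfd(d, theta, tau, z, alpha, pv, tp),
                 tolerance = 1e-8)
    expect_equal(mortality_log_posterior(d, theta, tau, z, a0, pm, tp),
                 oracle_lp_mortality(d, theta, tau, z, a0, pm, tp),
                 tolerance = 1e-8)
    expect_equal(duration_log_posterior(d, theta, tau, z, a0, sigma_res,
                                        pd, tp),
                 oracle_lp_duration(d, theta, tau, z, a0, sigma_res, pd, tp),
                 tolerance = 1e-8)
    expect_equal(subgroup_log_posterior(d, "bmi", theta, tau, z, a0, beta,
                                        gam, pm, pint, tp),
                 oracle_lp_subgroup(d, s, theta, tau, z, a0, beta, gam,
                                    pm, pint, tp),
                 tolerance = 1e-8)
  }
  # outside the support
  expect_identical(
    vfd_log_posterior(d, 0, -0.1, rep(0, 2), sort(rnorm(28)), pv, tp), -Inf)
  expect_identical(
    vfd_log_posterior(d, 0, 0.1, rep(0, 2), rep(0, 28), pv, tp), -Inf)
})

test_that("identical seed, data, and settings reproduce the draws", {
  d <- simulate_trial(sim_config(n_patients = 200, n_hospitals = 4,
                                 seed = 3))
  pr <- registry_prior(protocol_priors(), "mortality_28d", "neutral")
  f1 <- quiet_fit(fit_mortality_model(d, pr, chains = 2, warmup = 100,
                                      draws = 150, adapt = 150, seed = 42))
  f2 <- quiet_fit(fit_mortality_model(d, pr, chains = 2, warmup = 100,
                                      draws = 150, adapt = 150, seed = 42))
  expect_identical(f1$draws, f2$draws)
  f3 <- quiet_fit(fit_mortality_model(d, pr, chains = 2, warmup = 100,
                                      draws = 150, adapt = 150, seed = 43))
  expect_false(identical(f1$draws$theta, f3$draws$theta))
})

test_that("the mortality posterior tracks the contingency-table OR", {
  d <- mortality_fixture(100, 200, 150, 150)
  flat <- prior_spec("mortality_28d", "flat", 0, 10)
  fit <- quiet_fit(fit_mortality_model(
    d, flat, tau_prior = heterogeneity_prior(0.01),
    chains = 2, warmup = 400, draws = 800, adapt = 300, seed = 8))
  expect_equal(median(fit$draws$theta), log(oracle_contingency_or(d)),
               tolerance = 0.06)
})

test_that("the duration posterior tracks the two-sample mean difference", {
  d <- make_patients(
    arm = rep(c("lower_peep", "higher_peep"), each = 40),
    vfd = rep(20L, 80),
    died = rep(FALSE, 80),
    dur = c(rep(c(3.25, 4.75), 20), rep(c(4.25, 5.75), 20)))
  ols_md <- mean(d$vent_duration_days[d$arm == "lower_peep"]) -
    mean(d$vent_duration_days[d$arm == "higher_peep"])
  fit <- quiet_fit(fit_duration_model(
    d, prior_spec("duration", "flat", 0, 10),
    tau_prior = heterogeneity_prior(0.01),
    chains = 2, warmup = 400, draws = 800, adapt = 300, seed = 8))
  expect_equal(ols_md, -1)
  expect_equal(mean(fit$draws$theta), ols_md, tolerance = 0.12)
})

test_that("with no treatment information the posterior returns the prior", {
  d <- flat_likelihood_trial()
  pr <- prior_spec("mortality_28d", "neutral", 0, 0.35)
  fit <- quiet_fit(fit_mortality_model(d, pr, chains = 2, warmup = 300,
                                       draws = 600, adapt = 300, seed = 5))
  ess <- fit$diagnostics$ess[fit$diagnostics$param == "theta"]
  expect_lt(abs(mean(fit$draws$theta) - pr$mu), 3 * pr$sigma / sqrt(ess))
  expect_lt(abs(sd(fit$draws$theta) - pr$sigma),
            3 * pr$sigma / sqrt(2 * ess))
})

test_that("moving the prior mean toward benefit raises P(benefit)", {
  d <- simulate_trial(sim_config(n_patients = 400, seed = 21))
  p_benefit <- sapply(c(0.5, 0, -0.5), function(mu) {
    pr <- prior_spec("mortality_28d", sprintf("mu=%.1f", mu), mu, 0.35)
    fit <- quiet_fit(fit_mortality_model(d, pr, chains = 2, warmup = 300,
                                         draws = 500, adapt = 300,
                                         seed = 13))
    tail_probability(fit, "less", 0)
  })
  expect_true(all(diff(p_benefit) > 0))
})

test_that("degenerate model inputs fail loudly", {
  d <- tiny_trial()
  reg <- protocol_priors()
  one_level <- d
  one_level$vfd <- 5L
  one_level$died_by_day28 <- FALSE
  one_level$vent_duration_days <- 2
  expect_error(
    fit_vfd_model(one_level, registry_prior(reg, "vfd", "neutral")),
    "degenerate", class = "vfdbayes_validation_error")
  all_alive <- one_level
  expect_error(
    fit_mortality_model(all_alive,
                        registry_prior(reg, "mortality_28d", "neutral")),
    "single observed class", class = "vfdbayes_validation_error")
  one_survivor <- d
  one_survivor$died_by_day28[2] <- NA
  expect_error(
    suppressMessages(fit_duration_model(
      one_survivor[c(1, 2, 3, 5:8), ],
      registry_prior(reg, "duration", "neutral"))),
    "fewer than 2 survivors", class = "vfdbayes_validation_error")
})

test_that("an all-dead arm triggers a separation warning, prior dominates", {
  d <- make_patients(
    arm = rep(c("lower_peep", "higher_peep"), each = 15),
    vfd = c(rep(0L, 15), rep(20L, 10), rep(0L, 5)),
    died = c(rep(TRUE, 15), rep(FALSE, 10), rep(TRUE, 5)))
  expect_warning(
    quiet <- suppressMessages(fit_mortality_model(
      d, prior_spec("mortality_28d", "neutral", 0, 0.35),
      chains = 2, warmup = 200, draws = 200, adapt = 200, seed = 2)),
    class = "vfdbayes_separation_warning")
})

test_that("subgroup interaction models validate their design and recover", {
  reg <- protocol_priors()
  pm <- registry_prior(reg, "mortality_28d", "neutral")
  d <- tiny_trial()
  d$cardiac_arrest <- rep(TRUE, 8)
  expect_error(fit_subgroup_model(d, "cardiac_arrest", pm),
               "constant", class = "vfdbayes_validation_error")
  d$cardiac_arrest <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  # every cardiac-arrest patient is in the lower arm -> empty cell
  expect_error(fit_subgroup_model(d, "cardiac_arrest", pm),
               "empty subgroup cell", class = "vfdbayes_validation_error")

  # recovery: the effect exists only in one subgroup
  # baseline mortality 0.2 keeps the subgroup's death probability well
  # below the zero-VFD cell, so the generated interaction is not attenuated
  recovered <- sapply(1:6, function(r) {
    cfg <- sim_config(n_patients = 4000, true_log_or_mort = 0,
                      baseline_mort = 0.2,
                      interaction_covariate = "cardiac_arrest",
                      interaction_log_or = log(2), seed = 300 + r)
    fit <- quiet_fit(fit_subgroup_model(
      simulate_trial(cfg), "cardiac_arrest", pm,
      chains = 2, warmup = 300, draws = 500, adapt = 300, seed = 310 + r))
    gam <- median(fit$draws$gamma)
    gam > log(1.4) && gam < log(2.9)
  })
  expect_gte(sum(recovered), 4L)
})

test_that("a null interaction is covered by its credible interval", {
  reg <- protocol_priors()
  pm <- registry_prior(reg, "mortality_28d", "neutral")
  covered <- sapply(1:5, function(r) {
    d <- simulate_trial(sim_config(n_patients = 800, seed = 100 + r))
    fit <- quiet_fit(fit_subgroup_model(d, "surgical_admission", pm,
                                        chains = 2, warmup = 250,
                                        draws = 400, adapt = 250,
                                        seed = 200 + r))
    ci <- quantile(fit$draws$gamma, c(0.025, 0.975))
    ci[1] < 0 && ci[2] > 0
  })
  expect_gte(sum(covered), 4L)
})

test_that("collapsing the ordinal scale still estimates the common OR", {
  d <- simulate_trial(sim_config(n_patients = 2000, seed = 12))
  pr <- registry_prior(protocol_priors(), "vfd", "neutral")
  fit <- quiet_fit(fit_vfd_model(d, pr, chains = 2, warmup = 250,
                                 draws = 400, adapt = 250, seed = 6,
                                 collapse_breaks = c(0, 7, 14, 21, 28)))
  expect_identical(sum(grepl("^alpha", names(fit$draws))), 4L)
  ci <- quantile(fit$draws$theta, c(0.025, 0.975))
  expect_true(ci[1] < -0.165 && ci[2] > -0.165)
})
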