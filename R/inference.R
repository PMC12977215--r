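# Hierarchical Bayesian models of the analysis plan, sampled with JAGS.
#
# All three models share the structure: fixed treatment effect theta with the
# registry prior, hospital random intercepts b_h = tau * z_h (non-centred,
# z_h ~ N(0,1)) with tau ~ Half-Normal(0, tau_prior$sigma), and deliberately
# wide priors on nuisance parameters (Normal(0, 5) intercepts and ordered
# cut-points, Half-Normal(0, 5) residual SD) so the treatment prior dominates
# inference on theta. The ordinal and logistic likelihoods are passed to JAGS
# in sufficient-statistic form (multinomial / binomial counts per
# arm-by-hospital cell), identical to the per-patient likelihood up to a
# constant and much faster at trial scale.

NUISANCE_SD <- 5

#' Dichotomize a subgroup covariate
#'
#' Applies the prespecified subgroup cut-offs: BMI > 30, PaO2/FiO2 <= 200,
#' lung injury prediction score >= 4, APACHE >= 86; the three admission
#' covariates are already binary.
#'
#' @param data Patient table.
#' @param covariate One of `"cardiac_arrest"`, `"surgical_admission"`,
#'   `"primary_respiratory_failure"`, `"bmi"`, `"pf_ratio"`, `"lips"`,
#'   `"apache"`.
#' @return Logical vector (`NA` where the covariate is missing).
#' @export
subgroup_indicator <- function(data, covariate) {
  covariate <- arg_match0(covariate, covariate_columns())
  v <- data[[covariate]]
  switch(covariate,
         bmi = v > 30,
         pf_ratio = v <= 200,
         lips = v >= 4,
         apache = v >= 86,
         as.logical(v))
}

# ---- model strings -------------------------------------------------------

jags_common_block <- function() {
  "  for (j in 1:H) { z[j] ~ dnorm(0, 1); b[j] <- tau * z[j] }
  tau ~ dnorm(0, tau_prec) T(0,)
  theta ~ dnorm(mu_theta, prec_theta)"
}

jags_model_string <- function(outcome, interaction = FALSE) {
  lik <- switch(
    outcome,
    vfd = "  for (i in 1:C) {
    eta[i] <- theta * x[i] + b[h[i]]
    for (k in 1:K1) { q[i,k] <- ilogit(eta[i] - alpha[k]) }
    p[i,1] <- 1 - q[i,1]
    for (k in 2:K1) { p[i,k] <- q[i,k-1] - q[i,k] }
    p[i,K1+1] <- q[i,K1]
    ycnt[i,1:(K1+1)] ~ dmulti(p[i,1:(K1+1)], ncell[i])
  }
  alpha[1] ~ dnorm(0, nuis_prec)
  for (k in 2:K1) { alpha[k] ~ dnorm(0, nuis_prec) T(alpha[k-1],) }",
    mortality_28d = if (interaction) {
      "  for (i in 1:C) {
    logit(pr[i]) <- a0 + theta * x[i] + beta * s[i] + gamma * x[i] * s[i] + b[h[i]]
    deaths[i] ~ dbin(pr[i], ncell[i])
  }
  a0 ~ dnorm(0, nuis_prec)
  beta ~ dnorm(0, nuis_prec)
  gamma ~ dnorm(mu_gamma, prec_gamma)"
    } else {
      "  for (i in 1:C) {
    logit(pr[i]) <- a0 + theta * x[i] + b[h[i]]
    deaths[i] ~ dbin(pr[i], ncell[i])
  }
  a0 ~ dnorm(0, nuis_prec)"
    },
    duration = "  for (i in 1:N) {
    mu_y[i] <- a0 + theta * x[i] + b[h[i]]
    y[i] ~ dnorm(mu_y[i], prec_res)
  }
  a0 ~ dnorm(0, nuis_prec)
  sigma_res ~ dnorm(0, nuis_prec) T(0,)
  prec_res <- pow(sigma_res, -2)")
  paste0("model {\n", lik, "\n", jags_common_block(), "\n}\n")
}

# ---- diagnostics ---------------------------------------------------------

#' Split-chain R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift is detected as well as between-chain
#' disagreement.
#'
#' @param draws Matrix of draws, iterations x chains.
#' @return The split R-hat (1 indicates convergence).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  splits <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

fit_diagnostics <- function(samples, params) {
  ess_all <- coda::effectiveSize(samples)
  purrr::map(params, function(p) {
    mat <- sapply(samples, function(ch) as.numeric(ch[, p]))
    tibble(param = p, rhat = split_rhat(mat), ess = unname(ess_all[p]))
  }) %>% list_rbind()
}

# ---- data preparation ----------------------------------------------------

drop_incomplete <- function(data, cols, context) {
  keep <- complete.cases(data[, cols, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    inform(sprintf("%s: dropped %d incomplete row(s) (complete-case analysis)",
                   context, n_dropped))
  }
  list(data = data[keep, , drop = FALSE], n_dropped = n_dropped)
}

cell_index <- function(data) {
  x <- as.integer(as.character(data$arm) == "lower_peep")
  h <- as.integer(data$hospital_id)
  list(x = x, h = h, H = max(h))
}

# ---- the sampler front end ----------------------------------------------

run_jags <- function(model_string, jags_data, inits_fn, monitors, chains,
                     warmup, draws, adapt, seed) {
  base <- abs(as.integer(seed)) %% 2000000L
  inits <- purrr::map(seq_len(chains), function(c) {
    ini <- inits_fn(c)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- base * 1000L + c
    ini
  })
  model <- rjags::jags.model(textConnection(model_string), data = jags_data,
                             inits = inits, n.chains = chains,
                             n.adapt = adapt, quiet = TRUE)
  stats::update(model, n.iter = warmup, progress.bar = "none")
  rjags::coda.samples(model, variable.names = monitors, n.iter = draws,
                      progress.bar = "none")
}

theta_offsets <- function(chains) {
  rep_len(c(-0.5, 0.5, -1, 1, -1.5, 1.5), chains)
}

draws_tibble <- function(samples) {
  purrr::imap(samples, function(ch, i) {
    df <- as_tibble(as.matrix(ch), .name_repair = function(nm) {
      gsub("\\]", "", gsub("\\[", "_", nm))
    })
    df$.chain <- as.integer(i)
    df$.iteration <- seq_len(nrow(df))
    df
  }) %>% list_rbind()
}

new_peep_fit <- function(outcome, samples, prior, tau_prior, seed, n_obs,
                         n_dropped, extra = list()) {
  key_params <- intersect(c("theta", "tau", "gamma"),
                          coda::varnames(samples))
  diag_tbl <- fit_diagnostics(samples, coda::varnames(samples))
  key <- diag_tbl[diag_tbl$param %in% key_params, ]
  converged <- max(key$rhat) <= 1.01 && min(key$ess) >= 400
  if (max(key$rhat) > 1.01) {
    warn(sprintf("convergence flagged: split R-hat %.3f > 1.01 for '%s'",
                 max(key$rhat), key$param[which.max(key$rhat)]),
         class = "vfdbayes_convergence_warning")
  }
  structure(
    c(list(outcome = outcome, draws = draws_tibble(samples), prior = prior,
           tau_prior = tau_prior, seed = seed, n_obs = n_obs,
           n_dropped = n_dropped, diagnostics = diag_tbl,
           converged = converged),
      extra),
    class = "peep_fit")
}

#' @export
print.peep_fit <- function(x, ...) {
  cat(sprintf("<peep_fit> %s | prior %s: Normal(%.3g, %.3g) | n = %d (%d dropped)\n",
              x$outcome, x$prior$label, x$prior$mu, x$prior$sigma, x$n_obs,
              x$n_dropped))
  ci <- credible_interval(x)
  cat(sprintf("theta: median %.3f, 95%% CrI (%.3f, %.3f); converged: %s\n",
              median(x$draws$theta), ci[[1]], ci[[2]], x$converged))
  invisible(x)
}

# ---- model fits ----------------------------------------------------------

#' Fit the hierarchical cumulative logistic model for ventilator-free days
#'
#' Proportional-odds likelihood `P(VFD >= k) = plogis(theta * lower + b_h -
#' alpha_k)` over the full ordinal scale 0..28 (29 categories by default),
#' with ordered Normal(0, 5) cut-points, hospital random intercepts, and the
#' supplied treatment and heterogeneity priors. `theta > 0` (odds ratio > 1)
#' means higher cumulative odds of more ventilator-free days, i.e. benefit of
#' lower PEEP.
#'
#' @param data Patient table; rows with missing arm, hospital, or VFD are
#'   dropped (complete-case).
#' @param prior A [prior_spec()] for the treatment effect (log-OR scale).
#' @param tau_prior A [heterogeneity_prior()].
#' @param chains,warmup,draws,adapt Sampler settings (defaults 4 chains, 1000
#'   warmup, 1000 draws, 500 adaptation steps).
#' @param seed Integer seed; identical seed, data, and settings reproduce the
#'   draws exactly.
#' @param collapse_breaks Optional increasing integer vector of category upper
#'   bounds (last must be >= 28) to coarsen the ordinal scale, e.g.
#'   `c(0, 7, 14, 21, 28)`; the default keeps all 29 levels.
#' @return A `peep_fit` object: posterior draws of `theta` (log common OR),
#'   `tau`, and the cut-points, with split R-hat and effective-sample-size
#'   diagnostics. Non-convergence (split R-hat > 1.01) raises a warning of
#'   class `vfdbayes_convergence_warning`.
#' @export
fit_vfd_model <- function(data, prior, tau_prior = heterogeneity_prior(),
                          chains = 4, warmup = 1000, draws = 1000,
                          adapt = 500, seed = 1L, collapse_breaks = NULL) {
  stopifnot(inherits(prior, "prior_spec"), prior$outcome == "vfd",
            inherits(tau_prior, "heterogeneity_prior"))
  dc <- drop_incomplete(as_tibble(data), c("arm", "hospital_id", "vfd"),
                        "vfd model")
  d <- dc$data
  if (is.null(collapse_breaks)) {
    y <- as.integer(d$vfd) + 1L
    K <- 29L
  } else {
    stopifnot(!is.unsorted(collapse_breaks, strictly = TRUE),
              max(collapse_breaks) >= 28)
    y <- as.integer(cut(d$vfd, breaks = c(-1, collapse_breaks)))
    K <- length(collapse_breaks)
  }
  if (length(unique(y)) < 2L) {
    abort("degenerate VFD outcome: a single observed category",
          class = "vfdbayes_validation_error")
  }
  idx <- cell_index(d)
  cell <- interaction(idx$x, idx$h, drop = TRUE)
  ycnt <- unclass(table(cell, factor(y, levels = seq_len(K))))
  xh <- do.call(rbind, strsplit(rownames(ycnt), ".", fixed = TRUE))
  jags_data <- list(C = nrow(ycnt), K1 = K - 1L, H = idx$H,
                    x = as.integer(xh[, 1]), h = as.integer(xh[, 2]),
                    ycnt = ycnt, ncell = rowSums(ycnt),
                    tau_prec = tau_prior$sigma^-2,
                    mu_theta = prior$mu, prec_theta = prior$sigma^-2,
                    nuis_prec = NUISANCE_SD^-2)
  # start the cut-points at (clamped) empirical cumulative logits
  cum <- rev(cumsum(rev(tabulate(y, K) / length(y))))[-1L]
  alpha0 <- -qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  alpha0 <- cummax(alpha0) + seq(0, 1e-3, length.out = K - 1L)
  off <- theta_offsets(chains)
  inits_fn <- function(c) {
    list(theta = prior$mu + off[c] * prior$sigma,
         tau = tau_prior$sigma * (0.2 + 0.3 * ((c - 1L) %% 4L)),
         z = rep(0, idx$H), alpha = alpha0)
  }
  samples <- run_jags(jags_model_string("vfd"), jags_data, inits_fn,
                      c("theta", "tau", "alpha"), chains, warmup, draws,
                      adapt, seed)
  new_peep_fit("vfd", samples, prior, tau_prior, seed, nrow(d), dc$n_dropped)
}

#' Fit the hierarchical logistic model for 28-day mortality
#'
#' `logit P(death) = a0 + theta * lower + b_h`, with a wide Normal(0, 5)
#' intercept prior, hospital random intercepts, and the supplied treatment
#' and heterogeneity priors. `theta < 0` (odds ratio < 1) means benefit of
#' lower PEEP.
#'
#' @inheritParams fit_vfd_model
#' @param prior A [prior_spec()] for the treatment effect (log-OR scale).
#' @return A `peep_fit` (draws of `theta`, `tau`, intercept `a0`). An arm
#'   with all patients dead or all alive triggers a quasi-separation warning
#'   (the prior dominates).
#' @export
fit_mortality_model <- function(data, prior,
                                tau_prior = heterogeneity_prior(),
                                chains = 4, warmup = 1000, draws = 1000,
                                adapt = 500, seed = 1L) {
  stopifnot(inherits(prior, "prior_spec"), prior$outcome == "mortality_28d",
            inherits(tau_prior, "heterogeneity_prior"))
  dc <- drop_incomplete(as_tibble(data),
                        c("arm", "hospital_id", "died_by_day28"),
                        "mortality model")
  d <- dc$data
  if (length(unique(d$died_by_day28)) < 2L) {
    abort("degenerate mortality outcome: a single observed class",
          class = "vfdbayes_validation_error")
  }
  arm_rates <- tapply(d$died_by_day28, d$arm, mean)
  if (any(arm_rates %in% c(0, 1), na.rm = TRUE)) {
    warn("quasi-complete separation: an arm is all-dead or all-alive; the prior dominates",
         class = "vfdbayes_separation_warning")
  }
  idx <- cell_index(d)
  agg <- stats::aggregate(cbind(deaths = d$died_by_day28,
                                ncell = rep(1L, nrow(d))),
                          by = list(x = idx$x, h = idx$h), FUN = sum)
  jags_data <- list(C = nrow(agg), H = idx$H, x = agg$x, h = agg$h,
                    deaths = agg$deaths, ncell = agg$ncell,
                    tau_prec = tau_prior$sigma^-2,
                    mu_theta = prior$mu, prec_theta = prior$sigma^-2,
                    nuis_prec = NUISANCE_SD^-2)
  p_hat <- min(max(mean(d$died_by_day28), 0.02), 0.98)
  off <- theta_offsets(chains)
  inits_fn <- function(c) {
    list(theta = prior$mu + off[c] * prior$sigma,
         tau = tau_prior$sigma * (0.2 + 0.3 * ((c - 1L) %% 4L)),
         z = rep(0, idx$H), a0 = qlogis(p_hat))
  }
  samples <- run_jags(jags_model_string("mortality_28d"), jags_data,
                      inits_fn, c("theta", "tau", "a0"), chains, warmup,
                      draws, adapt, seed)
  new_peep_fit("mortality_28d", samples, prior, tau_prior, seed, nrow(d),
               dc$n_dropped)
}

#' Fit the hierarchical linear model for ventilation duration
#'
#' Among 28-day survivors only: `duration = a0 + theta * lower + b_h + eps`,
#' `eps ~ Normal(0, sigma_res^2)` with a Half-Normal(0, 5) prior on the
#' residual SD. `theta` is the mean difference in days; `theta < 0` means
#' benefit of lower PEEP.
#'
#' @inheritParams fit_vfd_model
#' @param prior A [prior_spec()] on the mean-difference (days) scale.
#' @return A `peep_fit` (draws of `theta`, `tau`, `a0`, `sigma_res`).
#' @export
fit_duration_model <- function(data, prior,
                               tau_prior = heterogeneity_prior(),
                               chains = 4, warmup = 1000, draws = 1000,
                               adapt = 500, seed = 1L) {
  stopifnot(inherits(prior, "prior_spec"), prior$outcome == "duration",
            inherits(tau_prior, "heterogeneity_prior"))
  d <- as_tibble(data)
  d <- d[d$died_by_day28 %in% FALSE, , drop = FALSE]
  dc <- drop_incomplete(d, c("arm", "hospital_id", "vent_duration_days"),
                        "duration model")
  d <- dc$data
  n_by_arm <- table(factor(d$arm, levels = arm_levels()))
  if (sum(n_by_arm) < 2L || any(n_by_arm == 1L)) {
    abort("fewer than 2 survivors with a recorded duration in an arm",
          class = "vfdbayes_validation_error")
  }
  idx <- cell_index(d)
  jags_data <- list(N = nrow(d), H = idx$H, x = idx$x, h = idx$h,
                    y = d$vent_duration_days,
                    tau_prec = tau_prior$sigma^-2,
                    mu_theta = prior$mu, prec_theta = prior$sigma^-2,
                    nuis_prec = NUISANCE_SD^-2)
  off <- theta_offsets(chains)
  inits_fn <- function(c) {
    list(theta = prior$mu + off[c] * prior$sigma,
         tau = tau_prior$sigma * (0.2 + 0.3 * ((c - 1L) %% 4L)),
         z = rep(0, idx$H), a0 = mean(d$vent_duration_days),
         sigma_res = max(sd(d$vent_duration_days), 0.1))
  }
  samples <- run_jags(jags_model_string("duration"), jags_data, inits_fn,
                      c("theta", "tau", "a0", "sigma_res"), chains, warmup,
                      draws, adapt, seed)
  new_peep_fit("duration", samples, prior, tau_prior, seed, nrow(d),
               dc$n_dropped)
}

#' Fit a treatment-by-subgroup interaction model for 28-day mortality
#'
#' Logistic model `logit P(death) = a0 + theta * lower + beta * subgroup +
#' gamma * lower * subgroup + b_h`, where the subgroup indicator follows the
#' prespecified cut-offs (see [subgroup_indicator()]). `gamma` is the
#' treatment-by-subgroup interaction on the log-OR scale, with its own prior.
#'
#' @inheritParams fit_mortality_model
#' @param covariate Subgroup covariate name (see [subgroup_indicator()]).
#' @param interaction_prior A [prior_spec()] for `gamma` (defaults to a
#'   weakly informative Normal(0, 1) on the log-OR scale).
#' @return A `peep_fit` whose draws include `gamma` (interaction) and `beta`
#'   (subgroup main effect); diagnostics cover `gamma` too.
#' @export
fit_subgroup_model <- function(data, covariate, prior,
                               interaction_prior =
                                 prior_spec("mortality_28d", "interaction",
                                            0, 1),
                               tau_prior = heterogeneity_prior(),
                               chains = 4, warmup = 1000, draws = 1000,
                               adapt = 500, seed = 1L) {
  stopifnot(inherits(prior, "prior_spec"), prior$outcome == "mortality_28d",
            inherits(interaction_prior, "prior_spec"))
  d <- as_tibble(data)
  d$.subgroup <- subgroup_indicator(d, covariate)
  dc <- drop_incomplete(d, c("arm", "hospital_id", "died_by_day28",
                             ".subgroup"),
                        sprintf("subgroup model (%s)", covariate))
  d <- dc$data
  if (length(unique(d$.subgroup)) < 2L) {
    abort(sprintf("subgroup indicator '%s' is constant: degenerate design",
                  covariate), class = "vfdbayes_validation_error")
  }
  cells <- table(d$arm, d$.subgroup)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    abort(sprintf("empty subgroup cell: arm '%s', %s = %s",
                  rownames(cells)[empty[1L]], covariate,
                  colnames(cells)[empty[2L]]),
          class = "vfdbayes_validation_error")
  }
  idx <- cell_index(d)
  s <- as.integer(d$.subgroup)
  agg <- stats::aggregate(cbind(deaths = d$died_by_day28,
                                ncell = rep(1L, nrow(d))),
                          by = list(x = idx$x, h = idx$h, s = s), FUN = sum)
  jags_data <- list(C = nrow(agg), H = idx$H, x = agg$x, h = agg$h,
                    s = agg$s, deaths = agg$deaths, ncell = agg$ncell,
                    tau_prec = tau_prior$sigma^-2,
                    mu_theta = prior$mu, prec_theta = prior$sigma^-2,
                    mu_gamma = interaction_prior$mu,
                    prec_gamma = interaction_prior$sigma^-2,
                    nuis_prec = NUISANCE_SD^-2)
  p_hat <- min(max(mean(d$died_by_day28), 0.02), 0.98)
  off <- theta_offsets(chains)
  inits_fn <- function(c) {
    list(theta = prior$mu + off[c] * prior$sigma,
         tau = tau_prior$sigma * (0.2 + 0.3 * ((c - 1L) %% 4L)),
         z = rep(0, idx$H), a0 = qlogis(p_hat), beta = 0,
         gamma = interaction_prior$mu)
  }
  samples <- run_jags(jags_model_string("mortality_28d", interaction = TRUE),
                      jags_data, inits_fn,
                      c("theta", "tau", "a0", "beta", "gamma"), chains,
                      warmup, draws, adapt, seed)
  new_peep_fit("mortality_28d", samples, prior, tau_prior, seed, nrow(d),
               dc$n_dropped,
               extra = list(interaction_covariate = covariate,
                            interaction_prior = interaction_prior))
}
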