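# Small deterministic datasets built in code.

make_patients <- function(arm, vfd, died, dur = NULL, hospital = NULL,
                          ...) {
  n <- length(arm)
  if (is.null(dur)) dur <- ifelse(died, NA_real_, 28 - vfd + 1)
  if (is.null(hospital)) hospital <- rep(1L, n)
  tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    hospital_id = as.integer(hospital),
    arm = factor(arm, levels = c("lower_peep", "higher_peep")),
    vfd = as.integer(vfd),
    died_by_day28 = died,
    vent_duration_days = dur,
    ...
  )
}

# deterministic 8-patient, 2-hospital fixture with 3 VFD levels
tiny_trial <- function() {
  make_patients(
    arm = rep(c("lower_peep", "higher_peep"), each = 4),
    vfd = c(0L, 10L, 25L, 25L, 0L, 0L, 10L, 25L),
    died = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    dur = c(NA, 18, 3, 2.5, NA, NA, 17.5, 3),
    hospital = c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L)
  )
}

# balanced two-arm mortality fixture with the given per-arm dead/alive counts
mortality_fixture <- function(dead_lower, alive_lower, dead_higher,
                              alive_higher) {
  n <- dead_lower + alive_lower + dead_higher + alive_higher
  died <- c(rep(TRUE, dead_lower), rep(FALSE, alive_lower),
            rep(TRUE, dead_higher), rep(FALSE, alive_higher))
  make_patients(
    arm = rep(c("lower_peep", "higher_peep"),
              c(dead_lower + alive_lower, dead_higher + alive_higher)),
    vfd = ifelse(died, 0L, 20L),
    died = died
  )
}

# no-treatment-information dataset: every patient in the reference arm
flat_likelihood_trial <- function(n = 40, seed = 11) {
  set.seed(seed)
  vfd <- sample(c(0L, 5L, 15L, 22L, 26L), n, replace = TRUE)
  died <- vfd == 0L & runif(n) < 0.8
  make_patients(
    arm = rep("higher_peep", n),
    vfd = vfd,
    died = died,
    dur = ifelse(died, NA_real_, round(exp(rnorm(n, log(4), 0.6)), 2)),
    hospital = rep(1:2, length.out = n)
  )
}

quiet_fit <- function(expr) suppressWarnings(suppressMessages(expr))

fast <- list(chains = 2, warmup = 300, draws = 400, adapt = 300)
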