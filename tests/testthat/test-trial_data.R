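test_that("compute_vfd reproduces the outcome definition on worked cases", {
  # died before day 28, still ventilated -> zero
  expect_identical(
    compute_vfd(data.frame(start = 0, end = 12), death_day = 10), 0L)
  # ventilated beyond day 28 -> zero
  expect_identical(compute_vfd(data.frame(start = 0, end = 29)), 0L)
  # extubated at day 3, alive, no reintubation -> days 3..27
  expect_identical(compute_vfd(data.frame(start = 0, end = 3)), 25L)
  # liberation never happens before the horizon -> zero even though the
  # mid-course unassisted window lasted >= 24h
  expect_identical(
    compute_vfd(data.frame(start = c(0, 5), end = c(2, 28))), 0L)
  # never ventilated, alive
  expect_identical(compute_vfd(NULL), 28L)
  # death after the horizon does not zero the count
  expect_identical(
    compute_vfd(data.frame(start = 0, end = 3), death_day = 30), 25L)
})

test_that("compute_vfd matches the brute-force day-marking oracle", {
  # single episode ending at t on a quarter-day grid
  for (t in seq(0.25, 27.75, by = 1.75)) {
    eps <- data.frame(start = 0, end = t)
    expect_identical(compute_vfd(eps), oracle_vfd(eps),
                     label = sprintf("terminal extubation at t=%.2f", t))
    expect_identical(compute_vfd(eps), as.integer(28 - ceiling(t)))
  }
  # reintubation courses with mid-course windows of varying length
  cases <- list(
    data.frame(start = c(0, 3.5), end = c(2, 6)),      # 1.5-day window
    data.frame(start = c(0, 2.5), end = c(2, 6)),      # 0.5-day window
    data.frame(start = c(0, 10), end = c(0.75, 12)),   # long gap
    data.frame(start = c(1, 5, 20), end = c(2, 6.25, 21)),
    data.frame(start = c(0, 27.5), end = c(26, 28.5))  # ventilated at horizon
  )
  for (i in seq_along(cases)) {
    expect_identical(compute_vfd(cases[[i]]), oracle_vfd(cases[[i]]),
                     label = sprintf("course %d", i))
  }
  # with a death day
  eps <- data.frame(start = c(0, 3.5), end = c(2, 6))
  for (dd in c(5, 20, 28, 29.5)) {
    expect_identical(compute_vfd(eps, death_day = dd),
                     oracle_vfd(eps, death_day = dd),
                     label = sprintf("death at %.1f", dd))
  }
})

test_that("compute_vfd respects its range, monotonicity, and options", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(1:3, 1)
    bounds <- sort(round(runif(2 * k, 0, 30) * 4) / 4)
    eps <- data.frame(start = bounds[seq(1, 2 * k, 2)],
                      end = bounds[seq(2, 2 * k, 2)])
    v <- compute_vfd(eps)
    expect_true(v >= 0L && v <= 28L)
    # extending ventilated time never increases VFD
    eps2 <- eps
    eps2$end[k] <- eps2$end[k] + 1
    if (k == 1 || eps2$end[k] > eps2$start[k]) {
      expect_lte(compute_vfd(eps2), v)
    }
  }
  # interrupted windows only count under the default policy
  eps <- data.frame(start = c(0, 5), end = c(2, 6))
  expect_identical(compute_vfd(eps), 25L)                      # 3 + 22
  expect_identical(compute_vfd(eps, count_interrupted = FALSE), 22L)
})

test_that("compute_vfd rejects malformed episode lists, naming the episode", {
  expect_error(compute_vfd(data.frame(start = 5, end = 3)),
               "episode 1.*end before start",
               class = "vfdbayes_validation_error")
  expect_error(compute_vfd(data.frame(start = c(0, 2), end = c(3, 6))),
               "episode 2 overlaps",
               class = "vfdbayes_validation_error")
})

test_that("trial tables round-trip through CSV field-for-field", {
  d <- simulate_trial(sim_config(n_patients = 100, n_hospitals = 3,
                                 seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(d, path)
  d2 <- read_trial_table(path)
  expect_identical(as.list(d2)[names(d)], as.list(d)[names(d)])
  expect_identical(attr(d2, "provenance"), "file")
  # booleans are written as lower-case literals
  expect_match(readLines(path, n = 2)[2], "(true|false)")
})

test_that("trial table validation rejects invariant violations by row", {
  good <- tiny_trial()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(good, path)
  expect_equal(nrow(read_trial_table(path)), 8L)

  bad_vfd <- good
  bad_vfd$vfd[3] <- 29L
  expect_error(validate_trial_data(bad_vfd), "0\\.\\.28.*row 3",
               class = "vfdbayes_validation_error")

  dead_nonzero <- good
  dead_nonzero$vfd[1] <- 3L
  expect_error(validate_trial_data(dead_nonzero), "died.*vfd = 0",
               class = "vfdbayes_validation_error")

  dead_with_duration <- good
  dead_with_duration$vent_duration_days[1] <- 4
  expect_error(validate_trial_data(dead_with_duration), "absent",
               class = "vfdbayes_validation_error")

  survivor_without_duration <- good
  survivor_without_duration$vent_duration_days[2] <- NA
  expect_error(validate_trial_data(survivor_without_duration),
               "required for survivors",
               class = "vfdbayes_validation_error")

  expect_error(validate_trial_data(good[good$arm == "lower_peep", ]),
               "both randomization arms",
               class = "vfdbayes_validation_error")
  expect_error(write_trial_table(good[0, ], path),
               class = "vfdbayes_validation_error")

  no_col <- good[, setdiff(names(good), "vfd")]
  expect_error(validate_trial_data(no_col), "missing mandatory column",
               class = "vfdbayes_validation_error")

  # missing covariates are permitted and filled as NA
  with_cov <- validate_trial_data(good)
  expect_true(all(is.na(with_cov$bmi)))
})
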