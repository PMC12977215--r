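#' Ventilator-free days from a ventilation course
#'
#' Computes the number of whole days a patient was alive and free of invasive
#' ventilation between randomization and `randomization_day + horizon`. A day
#' is the half-open interval `[k, k + 1)` on the study clock (origin at
#' randomization) and counts as ventilator-free only when the patient is
#' unassisted for its entirety and the unassisted period it belongs to lasted
#' at least `min_free_days` (24 consecutive hours by default). Patients who
#' died on or before the horizon, or who were still receiving invasive
#' ventilation at the horizon, score zero.
#'
#' @param episodes Data frame of ventilation episodes with numeric columns
#'   `start` and `end` (days, same origin as `randomization_day`), ordered and
#'   non-overlapping. `NULL` or a zero-row frame means the patient was never
#'   invasively ventilated. An episode whose `end` reaches the horizon means
#'   the patient was never liberated within the window and scores zero.
#' @param death_day Day of death on the same clock, or `NA` if the patient
#'   survived past follow-up.
#' @param randomization_day Day of randomization (default 0).
#' @param horizon Length of the assessment window in days (default 28).
#' @param min_free_days Minimum duration, in days, of an unassisted period for
#'   its whole days to count (default 1, i.e. 24 consecutive hours).
#' @param count_interrupted Should an unassisted window between two ventilation
#'   episodes (an extubation followed by reintubation) contribute free days
#'   when it lasts at least `min_free_days`? Default `TRUE`. Either way the
#'   patient must be off the ventilator at the horizon to score above zero.
#'
#' @return Integer number of ventilator-free days in `0:horizon`.
#' @examples
#' compute_vfd(data.frame(start = 0, end = 3))                      # 25
#' compute_vfd(data.frame(start = 0, end = 3), death_day = 10)      # 0
#' compute_vfd(data.frame(start = 0, end = 29))                     # 0
#' @export
compute_vfd <- function(episodes = NULL, death_day = NA, randomization_day = 0,
                        horizon = 28, min_free_days = 1,
                        count_interrupted = TRUE) {
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  if (is.null(episodes)) {
    episodes <- data.frame(start = numeric(0), end = numeric(0))
  }
  if (!all(c("start", "end") %in% names(episodes))) {
    abort("`episodes` must have columns `start` and `end`.",
          class = "vfdbayes_validation_error")
  }
  s <- as.numeric(episodes$start) - randomization_day
  e <- as.numeric(episodes$end) - randomization_day
  if (any(e < s)) {
    bad <- which(e < s)[1L]
    abort(sprintf("episode %d has end before start (%.3g < %.3g)",
                  bad, e[bad] + randomization_day, s[bad] + randomization_day),
          class = "vfdbayes_validation_error")
  }
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (length(s) > 1L && any(s[-1L] < e[-length(e)])) {
    bad <- which(s[-1L] < e[-length(e)])[1L] + 1L
    abort(sprintf("episode %d overlaps the preceding episode", bad),
          class = "vfdbayes_validation_error")
  }
  dd <- if (is.na(death_day)) NA_real_ else as.numeric(death_day) - randomization_day
  if (!is.na(dd) && dd < 0) {
    abort("`death_day` precedes `randomization_day`",
          class = "vfdbayes_validation_error")
  }
  if (!is.na(dd) && dd <= horizon) return(0L)
  # still on the ventilator at the horizon: never liberated within the window
  if (any(s < horizon & e >= horizon)) return(0L)

  # unassisted windows: before the first episode, between episodes, and after
  # the last episode; each runs until the next episode, death, or open-ended
  end_of_obs <- if (is.na(dd)) Inf else dd
  gap_start <- c(0, e)
  gap_end <- c(s, end_of_obs)
  keep <- gap_end > gap_start
  gap_start <- gap_start[keep]; gap_end <- gap_end[keep]
  if (length(gap_start) == 0L) return(0L)
  if (!count_interrupted) {
    # only the terminal unassisted period (ending at death/open follow-up)
    keep <- gap_end == end_of_obs
    gap_start <- gap_start[keep]; gap_end <- gap_end[keep]
  }
  qualifies <- (gap_end - gap_start) >= min_free_days
  free <- 0L
  for (i in which(qualifies)) {
    a <- gap_start[i]
    b <- min(gap_end[i], horizon)
    free <- free + max(0L, as.integer(floor(b) - ceiling(a)))
  }
  as.integer(min(free, horizon))
}

# ---- patient table validation -------------------------------------------

core_columns <- function() {
  c("patient_id", "hospital_id", "arm", "vfd", "died_by_day28",
    "vent_duration_days")
}

covariate_columns <- function() {
  c("cardiac_arrest", "surgical_admission", "primary_respiratory_failure",
    "bmi", "pf_ratio", "lips", "apache")
}

#' Validate a patient-level trial table
#'
#' Checks the invariants of the canonical patient table: ventilator-free days
#' (VFD) in `0:28`, patients who died by day 28 have zero VFD and no
#' ventilation duration, every survivor has a non-negative duration, hospital
#' identifiers are positive integers, and (by default) both randomization arms
#' are represented. Subgroup covariates may be missing (`NA`); missing
#' outcomes are not permitted.
#'
#' @param data Data frame with columns `patient_id`, `hospital_id`, `arm`
#'   (`"lower_peep"` / `"higher_peep"`), `vfd`, `died_by_day28`,
#'   `vent_duration_days`, and optionally the subgroup covariates
#'   `cardiac_arrest`, `surgical_admission`, `primary_respiratory_failure`,
#'   `bmi`, `pf_ratio`, `lips`, `apache`.
#' @param require_both_arms Require at least one patient per arm (default
#'   `TRUE`).
#' @return `data` (as a tibble, with covariate columns added as `NA` when
#'   absent), invisibly usable in a pipe. Errors of class
#'   `vfdbayes_validation_error` cite the violated invariant and row numbers.
#' @export
validate_trial_data <- function(data, require_both_arms = TRUE) {
  data <- as_tibble(data)
  missing_cols <- setdiff(core_columns(), names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "vfdbayes_validation_error")
  }
  for (cc in setdiff(covariate_columns(), names(data))) data[[cc]] <- NA
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0L) {
      problems <<- c(problems, sprintf(
        "%s (row%s %s)", what, if (length(rows) > 1L) "s" else "",
        paste(head(rows, 10L), collapse = ", ")))
    }
  }
  arm <- as.character(data$arm)
  note(which(!arm %in% arm_levels()),
       "arm must be 'lower_peep' or 'higher_peep'")
  hid <- data$hospital_id
  note(which(is.na(hid) | hid < 1 | hid != floor(hid)),
       "hospital_id must be a positive integer")
  vfd <- data$vfd
  note(which(is.na(vfd) | vfd < 0 | vfd > 28 | vfd != floor(vfd)),
       "vfd must be an integer in 0..28")
  died <- data$died_by_day28
  note(which(is.na(died)), "died_by_day28 must be TRUE or FALSE")
  note(which(died %in% TRUE & vfd > 0),
       "patients who died by day 28 must have vfd = 0")
  dur <- data$vent_duration_days
  note(which(died %in% TRUE & !is.na(dur)),
       "vent_duration_days must be absent for patients who died by day 28")
  note(which(died %in% FALSE & is.na(dur)),
       "vent_duration_days is required for survivors")
  note(which(!is.na(dur) & dur < 0), "vent_duration_days must be non-negative")
  if (require_both_arms &&
      !all(arm_levels() %in% arm)) {
    problems <- c(problems, "both randomization arms must be non-empty")
  }
  if (length(problems) > 0L) {
    abort(c("invalid trial table:", set_names(problems, "x")),
          class = "vfdbayes_validation_error")
  }
  data$arm <- factor(arm, levels = arm_levels())
  data$hospital_id <- as.integer(data$hospital_id)
  data$vfd <- as.integer(data$vfd)
  data
}

#' Read a patient-level trial table from CSV
#'
#' Reads the package's canonical exchange format: comma-separated, UTF-8,
#' mandatory header, booleans as `true`/`false` literals. Every row is
#' validated (see [validate_trial_data()]); offending rows are reported by
#' number.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of patient records with attributes
#'   `provenance = "file"` and `n_hospitals`.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "vfdbayes_io_error")
  }
  spec <- readr::cols(
    patient_id = readr::col_character(),
    hospital_id = readr::col_integer(),
    arm = readr::col_character(),
    vfd = readr::col_integer(),
    died_by_day28 = readr::col_logical(),
    vent_duration_days = readr::col_double(),
    cardiac_arrest = readr::col_logical(),
    surgical_admission = readr::col_logical(),
    primary_respiratory_failure = readr::col_logical(),
    bmi = readr::col_double(),
    pf_ratio = readr::col_double(),
    lips = readr::col_double(),
    apache = readr::col_double()
  )
  spec$cols <- spec$cols[intersect(names(spec$cols),
                                   names(readr::read_csv(path, n_max = 0,
                                                         show_col_types = FALSE)))]
  data <- readr::read_csv(path, col_types = spec, show_col_types = FALSE)
  data <- validate_trial_data(data)
  attr(data, "provenance") <- "file"
  attr(data, "n_hospitals") <- max(data$hospital_id)
  data
}

#' Write a patient-level trial table to CSV
#'
#' Validates the dataset and writes it in the canonical CSV dialect so that
#' `read_trial_table(write_trial_table(d, path))` reproduces `d`
#' field-for-field.
#'
#' @param data A patient table (see [validate_trial_data()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path) {
  data <- validate_trial_data(data)
  out <- data
  out$arm <- as.character(out$arm)
  for (col in names(out)) {          # booleans as true/false literals
    if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           ifelse(out[[col]], "true", "false"))
    }
  }
  readr::write_csv(out, path)
  invisible(path)
}
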