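# End-to-end orchestration: simulate (or load) -> fit every outcome x prior
# cell -> summarize, with an optional on-disk result bundle and a
# reproducibility manifest.

#' Configure a full analysis run
#'
#' @param data Data source: a [sim_config()] (the trial is simulated), a path
#'   to a canonical CSV (see [read_trial_table()]), or a patient table.
#' @param outcomes Outcomes to analyse (default all three).
#' @param priors Prior labels to run (default all four registry priors).
#' @param survey An [elicited_survey()] feeding the survey priors.
#' @param thresholds A [decision_thresholds()].
#' @param tau_prior A [heterogeneity_prior()].
#' @param chains,warmup,draws,adapt Sampler settings applied to every cell.
#' @param seed Master seed; per-cell fit seeds are derived from it
#'   arithmetically, so one seed pins down the entire bundle.
#' @param out_dir Optional output directory; when set, draws, diagnostics,
#'   summaries, and a manifest are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(data = sim_config(),
                       outcomes = outcome_levels(),
                       priors = prior_labels(),
                       survey = elicited_survey(),
                       thresholds = decision_thresholds(),
                       tau_prior = heterogeneity_prior(),
                       chains = 4, warmup = 1000, draws = 1000, adapt = 500,
                       seed = 1L, out_dir = NULL) {
  if (length(outcomes) == 0L || length(priors) == 0L) {
    abort("select at least one outcome and one prior",
          class = "vfdbayes_validation_error")
  }
  outcomes <- match.arg(outcomes, outcome_levels(), several.ok = TRUE)
  priors <- match.arg(priors, prior_labels(), several.ok = TRUE)
  structure(list(data = data, outcomes = outcomes, priors = priors,
                 survey = survey, thresholds = thresholds,
                 tau_prior = tau_prior, chains = chains, warmup = warmup,
                 draws = draws, adapt = adapt, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

resolve_data <- function(source, seed) {
  if (inherits(source, "sim_config")) {
    if (is.null(source$seed)) source$seed <- seed
    simulate_trial(source)
  } else if (is.character(source) && length(source) == 1L) {
    read_trial_table(source)
  } else {
    validate_trial_data(source)
  }
}

fit_for <- function(outcome) {
  switch(outcome, vfd = fit_vfd_model, mortality_28d = fit_mortality_model,
         duration = fit_duration_model)
}

#' Run the full analysis pipeline
#'
#' For every selected outcome-by-prior cell: builds the registry prior, fits
#' the hierarchical model, and produces the decision summary. Identical
#' master seeds reproduce the bundle exactly. When `out_dir` is set, each
#' cell's draws (CSV) and diagnostics (JSON), the combined summary table
#' (CSV + JSON), and a manifest with MD5 content hashes are written; a
#' failure in any cell aborts with the cell name, preserving the outputs
#' written so far.
#'
#' @param config A [run_config()].
#' @return A list of class `peep_bundle`: `summaries` (one row per cell),
#'   `fits` (named list of `peep_fit`s), `registry`, `data`, `config`,
#'   `manifest`.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  data <- withCallingHandlers(
    resolve_data(config$data, config$seed),
    error = function(e) {
      abort("stage 'data' failed", parent = e, class = "vfdbayes_stage_error")
    })
  registry <- protocol_priors(config$survey)
  grid <- tidyr::expand_grid(outcome = config$outcomes, prior = config$priors)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  files <- character(0)
  fits <- list()
  summaries <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    oc <- grid$outcome[i]
    pl <- grid$prior[i]
    cell <- paste(oc, pl, sep = "_")
    fit_seed <- (abs(config$seed) %% 20000000L) * 100L + i
    fit <- tryCatch(
      fit_for(oc)(data, prior = registry_prior(registry, oc, pl),
                  tau_prior = config$tau_prior, chains = config$chains,
                  warmup = config$warmup, draws = config$draws,
                  adapt = config$adapt, seed = fit_seed),
      error = function(e) {
        abort(sprintf("stage 'fit %s/%s' failed", oc, pl), parent = e,
              class = "vfdbayes_stage_error")
      })
    fits[[cell]] <- fit
    summaries[[i]] <- summarize_outcome(fit, config$thresholds)
    if (!is.null(out_dir)) {
      draws_path <- file.path(out_dir, paste0("draws_", cell, ".csv"))
      readr::write_csv(fit$draws, draws_path)
      diag_path <- file.path(out_dir, paste0("diagnostics_", cell, ".json"))
      jsonlite::write_json(
        list(cell = cell, seed = fit_seed, n = fit$n_obs,
             n_dropped = fit$n_dropped, converged = fit$converged,
             diagnostics = fit$diagnostics),
        diag_path, auto_unbox = TRUE, digits = NA)
      files <- c(files, draws_path, diag_path)
    }
  }
  summaries <- list_rbind(summaries)
  manifest <- NULL
  if (!is.null(out_dir)) {
    sum_csv <- file.path(out_dir, "summaries.csv")
    sum_json <- file.path(out_dir, "summaries.json")
    readr::write_csv(summaries, sum_csv)
    jsonlite::write_json(summaries, sum_json, auto_unbox = TRUE, digits = NA)
    files <- c(files, sum_csv, sum_json)
    manifest <- list(
      package = "vfdbayes",
      version = as.character(utils::packageVersion("vfdbayes")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      master_seed = config$seed,
      sampler = list(chains = config$chains, warmup = config$warmup,
                     draws = config$draws, adapt = config$adapt),
      files = purrr::map(set_names(files, basename(files)), function(f) {
        list(md5 = unname(tools::md5sum(f)))
      }))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  structure(list(summaries = summaries, fits = fits, registry = registry,
                 data = data, config = config, manifest = manifest),
            class = "peep_bundle")
}

#' @export
print.peep_bundle <- function(x, ...) {
  cat(sprintf("<peep_bundle> %d cells, master seed %d\n",
              nrow(x$summaries), x$config$seed))
  print(x$summaries[, c("outcome", "prior_label", "posterior_median",
                        "cri_lo", "cri_hi", "p_benefit", "classification")])
  invisible(x)
}

#' Render the report tables from a result bundle
#'
#' Produces the combined decision-summary table and, per outcome, a
#' prior-sensitivity table showing how the probability of benefit moves
#' across the priors. Errors if the bundle is missing any selected cell.
#'
#' @param bundle A `peep_bundle` from [run_full_analysis()].
#' @param out_dir Optional directory for CSV/JSON copies.
#' @return A list of class `peep_report` with tibbles `summary` and
#'   `sensitivity`.
#' @export
render_report <- function(bundle, out_dir = NULL) {
  stopifnot(inherits(bundle, "peep_bundle"))
  cfg <- bundle$config
  expected <- tidyr::expand_grid(outcome = cfg$outcomes,
                                 prior_label = cfg$priors)
  missing <- dplyr::anti_join(expected, bundle$summaries,
                              by = c("outcome", "prior_label"))
  if (nrow(missing) > 0L) {
    abort(c("incomplete bundle; missing cells:",
            set_names(paste(missing$outcome, missing$prior_label, sep = "/"),
                      "x")),
          class = "vfdbayes_validation_error")
  }
  sensitivity <- bundle$summaries %>%
    select("outcome", "prior_label", "p_benefit") %>%
    tidyr::pivot_wider(names_from = "prior_label",
                       values_from = "p_benefit")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(bundle$summaries, file.path(out_dir, "report_summary.csv"))
    jsonlite::write_json(bundle$summaries,
                         file.path(out_dir, "report_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(sensitivity,
                     file.path(out_dir, "report_sensitivity.csv"))
  }
  structure(list(summary = bundle$summaries, sensitivity = sensitivity),
            class = "peep_report")
}

#' @export
print.peep_report <- function(x, ...) {
  cat("Decision summary\n")
  print(x$summary[, c("outcome", "prior_label", "or_median", "p_benefit",
                      "p_rope", "classification")])
  cat("\nPrior sensitivity (probability of benefit)\n")
  print(x$sensitivity)
  invisible(x)
}

#' Plot prior sensitivity of the probability of benefit
#'
#' @param bundle A `peep_bundle`.
#' @return A ggplot object: probability of benefit by prior, one panel per
#'   outcome, with the superiority gate marked.
#' @export
plot_prior_sensitivity <- function(bundle) {
  stopifnot(inherits(bundle, "peep_bundle"))
  gate <- bundle$config$thresholds$superiority_prob
  ggplot2::ggplot(bundle$summaries,
                  ggplot2::aes(x = .data$prior_label, y = .data$p_benefit)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(yintercept = gate, linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "prior", y = "posterior probability of benefit") +
    ggplot2::theme_minimal()
}
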