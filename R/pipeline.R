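#' Run the full simulate -> predict -> ABC -> summarize pipeline
#'
#' Orchestrates every stage on synthetic data: generates the population,
#' exposure iterates and measured biomarkers, runs the forward
#' pharmacokinetic model for every participant-iterate (with freshly drawn
#' pharmacokinetic parameters and washing behavior per iterate), applies
#' the rejection-ABC rule at each configured threshold, and produces
#' survey-weighted percentile tables and unweighted fit diagnostics.
#'
#' Randomness is governed by `config$seed`: each stage re-seeds with a
#' fixed offset of the global seed (population +0, exposures +1000003,
#' true-world parameter draws +2500009, measurement noise +2000003,
#' prediction draws +3000003), so any stage can be rerun in isolation and
#' the whole run is byte-reproducible.
#'
#' @param config A [pipeline_config()] object.
#' @param output_dir Optional directory; if given, all tables are written
#'   there as CSV plus `diagnostics.json` and `manifest.json`.
#' @return (Invisibly) a list: `population`, `exposures`, `biomarkers`,
#'   `records` (participant-iterate predictions with `accepted_c*` flags),
#'   `filters` (per-threshold [filter_iterates()] results), `summary`
#'   (long percentile table), `diagnostics` (coverage, correlations,
#'   counts).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop("run_pipeline: 'config' must be a pipeline_config object")
  }
  cfg <- config$synth

  population <- generate_population(cfg)
  exposures <- generate_exposure_iterates(population, cfg)

  # measured world: true iterate 1 with its own parameter/behavior draws
  # (distinct offset from the one simulate_measurements re-seeds with)
  set.seed(cfg$seed + 2500009L)
  true_params <- sample_pk_parameters(nrow(population), config$priors,
                                      point_estimates = config$point_estimates)
  true_behavior <- sample_behavior(nrow(population), config$behavior)
  biomarkers <- simulate_measurements(population, exposures, true_params, cfg,
                                      true_behavior = true_behavior,
                                      constants = config$creatinine)

  # forward predictions for every participant-iterate
  set.seed(cfg$seed + 3000003L)
  params <- sample_pk_parameters(nrow(exposures), config$priors,
                                 point_estimates = config$point_estimates)
  behavior <- sample_behavior(nrow(exposures), config$behavior)
  preds <- predict_batch(population, exposures, params, behavior,
                         constants = config$creatinine, floor = config$floor)

  validate_biomarkers(biomarkers)
  measured <- standardize_measurement(biomarkers$urinary_3pba,
                                      biomarkers$creatinine)
  names(measured) <- biomarkers$participant_id

  records <- data.frame(
    participant_id = preds$participant_id,
    iterate = preds$iterate,
    predicted = preds$predicted_ugug,
    measured = as.numeric(measured[preds$participant_id]),
    exposure_day1 = preds$day1_dose,
    stringsAsFactors = FALSE
  )
  filters <- list()
  for (th in config$thresholds) {
    flag <- abc_accept(records$measured, records$predicted, th)
    records[[paste0("accepted_c", format(th, trim = TRUE))]] <- flag
    filters[[paste0("c=", format(th, trim = TRUE))]] <-
      filter_iterates(records, th)
  }

  summary <- summary_tables(records, population,
                            thresholds = config$thresholds,
                            n_cycles = config$n_cycles,
                            probs = config$probs)
  diagnostics <- pipeline_diagnostics(records, filters, config)

  result <- list(population = population, exposures = exposures,
                 biomarkers = biomarkers, records = records,
                 filters = filters, summary = summary,
                 diagnostics = diagnostics, config = config)
  if (!is.null(output_dir)) {
    write_pipeline_outputs(result, output_dir)
  }
  invisible(result)
}

pipeline_diagnostics <- function(records, filters, config) {
  diag <- list(
    n_participants = length(unique(records$participant_id)),
    n_records = nrow(records),
    coverage = lapply(stats::setNames(config$thresholds,
                                      paste0("c", format(config$thresholds,
                                                         trim = TRUE))),
                      function(th) coverage_fraction(records, th)),
    correlation = list(), dropped = list()
  )
  r_unf <- log_correlation(records, floor = config$floor)
  diag$correlation$unfiltered <- list(log10_r = as.numeric(r_unf),
                                      raw_r = attr(r_unf, "raw_r"))
  for (nm in names(filters)) {
    acc <- filters[[nm]]$accepted
    diag$dropped[[nm]] <- length(filters[[nm]]$dropped_participants)
    diag$correlation[[nm]] <- if (nrow(acc) >= 3L) {
      r <- log_correlation(acc, floor = config$floor)
      list(log10_r = as.numeric(r), raw_r = attr(r, "raw_r"))
    } else {
      list(log10_r = NA_real_, raw_r = NA_real_)
    }
  }
  diag
}

#' Write pipeline artifacts to disk
#'
#' Emits the on-disk schemas: `participants.csv`, `diet.csv`,
#' `design.csv`, `exposures.csv`, `biomarkers.csv`, `predictions.csv`
#' (with acceptance flags), one `accepted_c*.csv` per threshold,
#' `summary_tables.csv` (long format), `diagnostics.json`, and
#' `manifest.json` (seed, sizes, configuration echo). All hours are
#' integer and 0-based; day-1 hour 0 is the midnight starting the first
#' recall day.
#'
#' @param result List returned by [run_pipeline()].
#' @param output_dir Directory to create/write into.
#' @return (Invisibly) the output directory path.
#' @export
write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  }
  pop <- result$population
  wr(pop[, c("participant_id", "age", "sex", "body_weight", "height",
             "collection_hour", "fasting_hours")], "participants.csv")
  wr(as_diet_table(pop), "diet.csv")
  wr(pop[, c("participant_id", "survey_weight", "stratum", "psu", "cycle")],
     "design.csv")
  wr(result$exposures, "exposures.csv")
  wr(result$biomarkers, "biomarkers.csv")
  wr(result$records, "predictions.csv")
  for (nm in names(result$filters)) {
    wr(result$filters[[nm]]$accepted,
       paste0("accepted_", gsub("[=.]", "", nm), ".csv"))
  }
  wr(result$summary, "summary_tables.csv")
  jsonlite::write_json(result$diagnostics,
                       file.path(output_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    seed = result$config$seed,
    n_participants = result$config$synth$n_participants,
    n_iterates = result$config$synth$n_iterates,
    thresholds = result$config$thresholds,
    point_estimates = result$config$point_estimates,
    n_records = nrow(result$records)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
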