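# internal schema checks; fail fast with the offending column/field named

validate_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

validate_population <- function(population) {
  validate_columns(population,
                   c("participant_id", "age", "sex", "body_weight", "height",
                     "meal_hours", "collection_hour", "fasting_hours",
                     "survey_weight", "stratum", "psu", "cycle"),
                   "population")
  if (any(lengths(population$meal_hours) == 0L)) {
    stop("population: every participant must report at least one meal hour",
         call. = FALSE)
  }
  if (any(population$collection_hour < 0) || any(population$collection_hour > 23)) {
    stop("population: 'collection_hour' must lie in 0..23", call. = FALSE)
  }
  if (any(population$fasting_hours < 0)) {
    stop("population: 'fasting_hours' must be >= 0", call. = FALSE)
  }
  if (any(population$body_weight <= 0) || any(population$height <= 0)) {
    stop("population: 'body_weight' and 'height' must be positive", call. = FALSE)
  }
  if (any(population$survey_weight <= 0)) {
    stop("population: 'survey_weight' must be positive", call. = FALSE)
  }
  invisible(population)
}

validate_biomarkers <- function(biomarkers) {
  validate_columns(biomarkers,
                   c("participant_id", "urinary_3pba", "creatinine",
                     "below_lod"), "biomarkers")
  if (any(biomarkers$urinary_3pba <= 0)) {
    stop("biomarkers: 'urinary_3pba' must be positive after LOD substitution",
         call. = FALSE)
  }
  if (any(biomarkers$creatinine <= 0)) {
    stop("biomarkers: 'creatinine' must be positive", call. = FALSE)
  }
  invisible(biomarkers)
}
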