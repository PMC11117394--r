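#' Generate a synthetic survey population
#'
#' Emulates the structure of a national health-survey sample: ages spanning
#' children (6-11), adolescents (12-19), adults (20-59) and seniors (60-79);
#' sex-specific heights and weights (growth-curve based below 20 y); 1-5
#' daily meals drawn from a clustered breakfast/lunch/dinner/snack pattern;
#' an exam (urine-collection) hour on day 2 between 08:00 and 19:00;
#' reported pre-collection fasting times; positive exam sampling weights;
#' and a two-pseudo-cycle stratified design (stratum, PSU, cycle) so the
#' cycle-pooling weight rule can be exercised.
#'
#' @param cfg A [synth_config()] object.
#' @return Data frame with one row per participant: `participant_id`,
#'   `age`, `sex`, `body_weight`, `height`, `meal_hours` (list column of
#'   integer hours 0-23), `collection_hour`, `fasting_hours`,
#'   `survey_weight`, `stratum`, `psu`, `cycle`. Deterministic given
#'   `cfg$seed`.
#' @export
generate_population <- function(cfg) {
  if (!inherits(cfg, "synth_config")) {
    stop("generate_population: 'cfg' must be a synth_config object")
  }
  set.seed(cfg$seed)
  n <- cfg$n_participants

  grp <- sample(c("child", "adolescent", "adult", "senior"), n,
                replace = TRUE, prob = c(0.15, 0.15, 0.50, 0.20))
  age <- integer(n)
  age[grp == "child"] <- sample(6:11, sum(grp == "child"), replace = TRUE)
  age[grp == "adolescent"] <- sample(12:19, sum(grp == "adolescent"), replace = TRUE)
  age[grp == "adult"] <- sample(20:59, sum(grp == "adult"), replace = TRUE)
  age[grp == "senior"] <- sample(60:79, sum(grp == "senior"), replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)

  height <- numeric(n)
  young <- age < 20
  height[young] <- 112 + (age[young] - 6) * 4.6 + stats::rnorm(sum(young), 0, 5)
  height[!young] <- ifelse(sex[!young] == "male",
                           stats::rnorm(sum(!young), 176, 7),
                           stats::rnorm(sum(!young), 163, 6))
  height <- pmax(height, 95)
  bmi <- ifelse(young, pmax(stats::rnorm(n, 18.5, 2.5), 13),
                pmax(stats::rnorm(n, 26.5, 4.5), 16))
  body_weight <- round(bmi * (height / 100)^2, 1)

  n_meals <- sample(1:5, n, replace = TRUE,
                    prob = c(0.05, 0.15, 0.45, 0.25, 0.10))
  meal_hours <- vector("list", n)
  for (i in seq_len(n)) {
    mains <- c(sample(6:9, 1L), sample(11:13, 1L), sample(17:20, 1L))
    m <- n_meals[i]
    hrs <- if (m <= 3L) sort(sample(mains, m)) else {
      sort(c(mains, sample(c(10L, 14:16, 21L), m - 3L)))
    }
    meal_hours[[i]] <- as.integer(hrs)
  }

  pop <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex, body_weight = body_weight,
    height = round(height, 1),
    collection_hour = sample(8:19, n, replace = TRUE),
    fasting_hours = round(stats::rgamma(n, shape = 2.2, scale = 2.5), 1),
    survey_weight = round(stats::rlnorm(n, log(12000), 0.5), 1),
    stratum = sample(1:15, n, replace = TRUE),
    psu = sample(1:2, n, replace = TRUE),
    cycle = sample(1:2, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  pop$meal_hours <- meal_hours
  validate_population(pop)
  pop
}

#' Generate per-iterate daily exposure estimates
#'
#' Stand-in for the per-iterate acute Monte Carlo output of a regulatory
#' dietary exposure model: for every participant and iterate, day-1 and
#' day-2 daily doses are drawn independently (episodic exposure) from the
#' configured log-normal on the mg/kg/day scale.
#'
#' @param population Data frame from [generate_population()].
#' @param cfg A [synth_config()] object; `cfg$n_iterates` iterates are
#'   drawn per participant (default 5).
#' @return Data frame with `participant_id`, `iterate`, `day1_dose`,
#'   `day2_dose` (mg/kg/day); `n_participants * n_iterates` rows, ordered
#'   by participant then iterate. Deterministic given `cfg$seed`.
#' @export
generate_exposure_iterates <- function(population, cfg) {
  if (!inherits(cfg, "synth_config")) {
    stop("generate_exposure_iterates: 'cfg' must be a synth_config object")
  }
  validate_population(population)
  if (nrow(population) == 0L) {
    stop("generate_exposure_iterates: 'population' is empty")
  }
  set.seed(cfg$seed + 1000003L)
  n <- nrow(population) * cfg$n_iterates
  out <- data.frame(
    participant_id = rep(population$participant_id, each = cfg$n_iterates),
    iterate = rep(seq_len(cfg$n_iterates), times = nrow(population)),
    day1_dose = stats::rlnorm(n, cfg$daily_dose_logmean, cfg$daily_dose_logsd),
    day2_dose = stats::rlnorm(n, cfg$daily_dose_logmean, cfg$daily_dose_logsd),
    stringsAsFactors = FALSE
  )
  out
}

#' Simulate measured urinary biomarkers from a designated true iterate
#'
#' Closes the generative loop for parameter-recovery experiments: one
#' iterate per participant is designated as the truth, pushed through the
#' forward model under supplied "true" pharmacokinetic parameters and
#' behavior, multiplied by log10-normal measurement/model error, converted
#' to a ug/L concentration via a simulated urinary creatinine, and censored
#' at the limit of detection with the LOD/sqrt(2) substitution.
#'
#' @param population Data frame from [generate_population()].
#' @param exposures Data frame from [generate_exposure_iterates()]; must
#'   contain `true_iterate` for every participant.
#' @param true_params Data frame of pharmacokinetic parameters, one row per
#'   participant (aligned with `population`).
#' @param cfg A [synth_config()] object (`lod`, `measurement_noise_logsd`).
#' @param true_iterate Which iterate index is the truth (default 1).
#' @param true_behavior Optional data frame of behavior draws, one row per
#'   participant; if NULL, drawn from [behavior_config()] defaults.
#' @param constants A [creatinine_constants()] object.
#' @return Data frame with `participant_id`, `urinary_3pba` (ug/L),
#'   `creatinine` (mg/dL), `below_lod` (logical). Deterministic given
#'   `cfg$seed`.
#' @export
simulate_measurements <- function(population, exposures, true_params, cfg,
                                  true_iterate = 1L, true_behavior = NULL,
                                  constants = creatinine_constants()) {
  if (!inherits(cfg, "synth_config")) {
    stop("simulate_measurements: 'cfg' must be a synth_config object")
  }
  validate_population(population)
  truth <- exposures[exposures$iterate == true_iterate, , drop = FALSE]
  truth <- truth[match(population$participant_id, truth$participant_id), ,
                 drop = FALSE]
  if (anyNA(truth$participant_id)) {
    stop("simulate_measurements: some participants lack the designated true iterate")
  }
  if (nrow(true_params) != nrow(population)) {
    stop("simulate_measurements: 'true_params' must have one row per participant")
  }
  set.seed(cfg$seed + 2000003L)
  if (is.null(true_behavior)) {
    true_behavior <- sample_behavior(nrow(population))
  }
  pred <- predict_batch(population, truth, true_params, true_behavior,
                        constants = constants)$predicted_ugug

  creatinine <- pmin(pmax(stats::rlnorm(nrow(population), log(110), 0.4), 10), 400)
  eps <- stats::rnorm(nrow(population), 0, cfg$measurement_noise_logsd)
  ugL <- pred * creatinine * 1e4 * 10^eps
  below <- ugL < cfg$lod
  ugL[below] <- cfg$lod / sqrt(2)
  data.frame(participant_id = population$participant_id,
             urinary_3pba = ugL, creatinine = creatinine,
             below_lod = below, stringsAsFactors = FALSE)
}

#' Simulate a controlled single-bolus dosing study
#'
#' Generates the structure of an oral-dosing validation study: a small
#' panel of adult volunteers each receives one oral lambda-cyhalothrin
#' bolus at t = 0 and has creatinine-standardized urinary 3PBA evaluated
#' repeatedly at the requested times over the following 120 hours, under
#' individually sampled pharmacokinetic parameters (no pre-study exposure,
#' so the initial serum concentration is zero).
#'
#' @param n_subjects Number of volunteers (default 6).
#' @param dose_mg_per_kg Single oral bolus (mg per kg body weight),
#'   ingested during hour 0.
#' @param sampling_hours Integer sampling times within \[0, 120\] hours
#'   post-dose.
#' @param seed Integer seed.
#' @param priors A [pk_priors()] object.
#' @param constants A [creatinine_constants()] object.
#' @return Data frame with `subject`, `hour`, `urinary_3pba_ugug`
#'   (bladder-averaged, creatinine-standardized). Deterministic given
#'   `seed`.
#' @export
generate_dosing_study_fixture <- function(n_subjects = 6L,
                                          dose_mg_per_kg = 1e-3,
                                          sampling_hours = seq(0L, 120L, by = 4L),
                                          seed = 1L,
                                          priors = pk_priors(),
                                          constants = creatinine_constants()) {
  sampling_hours <- as.integer(sampling_hours)
  if (any(sampling_hours < 0L) || any(sampling_hours > 120L)) {
    stop("generate_dosing_study_fixture: 'sampling_hours' must lie within [0, 120]")
  }
  if (dose_mg_per_kg < 0) {
    stop("generate_dosing_study_fixture: 'dose_mg_per_kg' must be >= 0")
  }
  set.seed(seed)
  params <- sample_pk_parameters(n_subjects, priors)
  age <- sample(25:45, n_subjects, replace = TRUE)
  sex <- sample(c("male", "female"), n_subjects, replace = TRUE)
  height <- ifelse(sex == "male", stats::rnorm(n_subjects, 176, 7),
                   stats::rnorm(n_subjects, 163, 6))
  weight <- pmax(stats::rnorm(n_subjects, 26, 4), 18) * (height / 100)^2
  N <- creatinine_excretion_rate(age, sex, weight, height, constants)

  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- params[i, , drop = FALSE]
    doses <- c(dose_mg_per_kg * weight[i], numeric(120L))  # bolus in hour 0
    serum <- serum_series(p, doses, C0 = 0)
    urine <- urine_entering_bladder(p, serum, N[i])
    conc <- vapply(sampling_hours, function(h) {
      bladder_average(urine, h, p$void_interval)
    }, numeric(1L))
    out[[i]] <- data.frame(subject = i, hour = sampling_hours,
                           urinary_3pba_ugug = conc)
  }
  do.call(rbind, out)
}

#' Long-format meal table for a population
#'
#' Unnests the `meal_hours` list column into the on-disk diet schema
#' (one row per participant-meal).
#'
#' @param population Data frame from [generate_population()].
#' @return Data frame with `participant_id`, `meal_hour`.
#' @export
as_diet_table <- function(population) {
  validate_population(population)
  data.frame(
    participant_id = rep(population$participant_id,
                         lengths(population$meal_hours)),
    meal_hour = unlist(population$meal_hours),
    stringsAsFactors = FALSE
  )
}
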