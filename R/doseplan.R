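#' Split a daily dose equally across reported meal hours
#'
#' Regulatory dietary models report total daily exposure without meal-level
#' detail, so the day's dose is divided equally among the meals the
#' participant reported, each consumed within its reported clock hour.
#'
#' @param daily_dose_mg Total ingested lambda-cyhalothrin for the day (mg).
#' @param meal_hours Integer hours of day (0-23) at which meals were eaten.
#' @return Named numeric vector over hours 0-23 (names "0".."23"); meal
#'   hours carry `daily_dose_mg / length(meal_hours)`, all others zero.
#' @export
split_daily_dose <- function(daily_dose_mg, meal_hours) {
  if (length(meal_hours) == 0L) {
    stop("split_daily_dose: 'meal_hours' is empty; a participant must report at least one meal")
  }
  meal_hours <- as.integer(meal_hours)
  if (anyNA(meal_hours) || any(meal_hours < 0L) || any(meal_hours > 23L)) {
    stop("split_daily_dose: 'meal_hours' must be integers in 0..23")
  }
  if (anyDuplicated(meal_hours)) {
    stop("split_daily_dose: 'meal_hours' must be distinct")
  }
  if (!is.numeric(daily_dose_mg) || length(daily_dose_mg) != 1L ||
      is.na(daily_dose_mg) || daily_dose_mg < 0) {
    stop("split_daily_dose: 'daily_dose_mg' must be a single non-negative number")
  }
  out <- numeric(24L)
  names(out) <- as.character(0:23)
  out[meal_hours + 1L] <- daily_dose_mg / length(meal_hours)
  out
}

#' Meals retained on the urine-collection day
#'
#' No food diary exists for the collection day itself, so its meals are
#' assumed to repeat the previous day's mealtimes and per-meal doses.
#' Meals inconsistent with the reported pre-collection fast are dropped:
#' hour `h` is retained iff `h < collection_hour - fasting_hours`
#' (a meal exactly at the fasting boundary would contradict the fast).
#'
#' @param meal_hours_day1 Integer day-1 meal hours (0-23).
#' @param collection_hour Integer hour of day of urine collection on day 2.
#' @param fasting_hours Reported fasting time before collection (h, >= 0).
#' @return Integer vector of retained day-2 meal hours (possibly empty).
#' @export
build_collection_day_meals <- function(meal_hours_day1, collection_hour,
                                       fasting_hours) {
  if (!is.numeric(collection_hour) || length(collection_hour) != 1L ||
      collection_hour < 0 || collection_hour > 23) {
    stop("build_collection_day_meals: 'collection_hour' must be in 0..23")
  }
  if (!is.numeric(fasting_hours) || length(fasting_hours) != 1L ||
      is.na(fasting_hours) || fasting_hours < 0) {
    stop("build_collection_day_meals: 'fasting_hours' must be >= 0")
  }
  mh <- as.integer(meal_hours_day1)
  mh[mh < collection_hour - fasting_hours]
}

#' Draw food-washing behavior for one or more participant-iterates
#'
#' Washer status is Bernoulli(`washer_prob`); for washers the residue
#' reduction factor is drawn from Beta(`washing_shape1`, `washing_shape2`).
#' Behavior is redrawn independently for every participant-iterate.
#' Uses the current R random number stream.
#'
#' @param n Number of draws.
#' @param behavior A [behavior_config()] object.
#' @return Data frame with logical `is_washer` and numeric `washing_factor`
#'   in \[0, 1\] (drawn for every row; ignored downstream for non-washers).
#' @export
sample_behavior <- function(n, behavior = behavior_config()) {
  stopifnot(inherits(behavior, "behavior_config"))
  n <- as.integer(n)
  data.frame(
    is_washer = stats::runif(n) < behavior$washer_prob,
    washing_factor = stats::rbeta(n, behavior$washing_shape1,
                                  behavior$washing_shape2)
  )
}

#' Apply the washing reduction to a daily dose
#'
#' Washers have their ingested dose reduced by the drawn washing factor;
#' non-washers are unaffected.
#'
#' @param daily_dose_mg Non-negative dose (mg); vectorized.
#' @param behavior Data frame (or one-row list) with `is_washer` and
#'   `washing_factor`, recycled against `daily_dose_mg`.
#' @return Adjusted dose, `dose * (1 - washing_factor)` for washers.
#' @export
apply_washing <- function(daily_dose_mg, behavior) {
  if (any(daily_dose_mg < 0, na.rm = TRUE)) {
    stop("apply_washing: doses must be non-negative")
  }
  wf <- behavior$washing_factor
  if (any(wf < 0 | wf > 1, na.rm = TRUE)) {
    stop("apply_washing: 'washing_factor' must lie in [0, 1]")
  }
  daily_dose_mg * ifelse(behavior$is_washer, 1 - wf, 1)
}

#' Mean hourly intake rate for the steady-state initial condition
#'
#' Before the first recall day there is no dietary information, so prior
#' intake is represented by the washing-adjusted average of the two
#' recalled daily doses, spread uniformly over 24 h. The pharmacokinetic
#' module converts this rate into a steady-state serum concentration used
#' as the initial condition at midnight of recall day 1.
#'
#' @param day1_dose_mgkg,day2_dose_mgkg Daily doses (mg/kg/day).
#' @param body_weight_kg Body weight (kg).
#' @param behavior Behavior draw as in [apply_washing()].
#' @return Mean intake rate in mg/h.
#' @export
steady_state_initial_rate <- function(day1_dose_mgkg, day2_dose_mgkg,
                                      body_weight_kg, behavior) {
  if (any(body_weight_kg <= 0)) {
    stop("steady_state_initial_rate: 'body_weight_kg' must be > 0")
  }
  if (any(day1_dose_mgkg < 0) || any(day2_dose_mgkg < 0)) {
    stop("steady_state_initial_rate: doses must be >= 0")
  }
  daily_mg <- (day1_dose_mgkg + day2_dose_mgkg) / 2 * body_weight_kg
  apply_washing(daily_mg, behavior) / 24
}

#' Build the hour-indexed ingestion schedule for one participant-iterate
#'
#' Composes the dose-splitting, collection-day meal retention, washing
#' adjustment and steady-state initialization into a single schedule
#' covering hours t = 0 (midnight starting recall day 1) through
#' T = 24 + collection_hour (the collection time on day 2). Dose entries
#' are mg ingested during hour \[t, t+1); the entry at hour T is always
#' zero (collection precedes any further intake).
#'
#' @param individual One-row data frame (or list) with `participant_id`,
#'   `body_weight`, `collection_hour`, `fasting_hours`, and `meal_hours`
#'   (integer vector, possibly as a length-1 list column).
#' @param day1_dose_mgkg,day2_dose_mgkg Per-iterate daily exposures
#'   (mg/kg/day).
#' @param behavior One-row behavior draw ([sample_behavior()]).
#' @param iterate Iterate index carried through for bookkeeping.
#' @return Object of class `dose_schedule`: list with `participant_id`,
#'   `iterate`, `hours` (0..T), `doses` (mg per hour slot),
#'   `day1_daily_dose_mg` (washing-adjusted), `initial_rate` (mg/h),
#'   `collection_index` (= T).
#' @export
build_schedule <- function(individual, day1_dose_mgkg, day2_dose_mgkg,
                           behavior, iterate = 1L) {
  mh <- individual$meal_hours
  if (is.list(mh)) mh <- mh[[1L]]
  bw <- individual$body_weight
  day1_mg <- apply_washing(day1_dose_mgkg * bw, behavior)
  per_hour_day1 <- split_daily_dose(day1_mg, mh)
  keep <- build_collection_day_meals(mh, individual$collection_hour,
                                     individual$fasting_hours)
  T_idx <- 24L + as.integer(individual$collection_hour)
  doses <- numeric(T_idx + 1L)
  doses[1:24] <- per_hour_day1
  if (length(keep) > 0L) {
    # same per-meal dose as day 1
    doses[keep + 24L + 1L] <- day1_mg / length(mh)
  }
  sched <- structure(
    list(participant_id = individual$participant_id,
         iterate = iterate,
         hours = 0:T_idx,
         doses = doses,
         day1_daily_dose_mg = day1_mg,
         initial_rate = steady_state_initial_rate(day1_dose_mgkg,
                                                  day2_dose_mgkg, bw,
                                                  behavior),
         collection_index = T_idx),
    class = "dose_schedule")
  d1 <- sum(sched$doses[1:24])
  if (day1_mg > 0 && abs(d1 - day1_mg) > 1e-9 * day1_mg) {
    stop("build_schedule: day-1 dose mass not conserved")
  }
  sched
}
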