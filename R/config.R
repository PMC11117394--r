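#' Prior distributions for the 3PBA pharmacokinetic parameters
#'
#' Returns the hyperparameters of the Monte Carlo priors used when sampling
#' per-iterate pharmacokinetic parameters. Defaults reproduce the published
#' 3PBA kinetics: elimination half-life ~ Gamma(shape 24.2, rate 3.79) hours
#' (so the implied mean half-life is 6.39 h and the mean elimination rate
#' `k = ln(2)/t_half` is near the 0.108 1/h point estimate), absorbed-and-
#' metabolized fraction `f` ~ Beta(11.1, 31.4) (mean 0.261, point estimate
#' 0.25), volume of distribution `V` ~ Gamma(shape 6.78, rate 0.38) L (mean
#' 17.84 L, point estimate 17.7 L), 3PBA share of total urinary metabolite
#' `R` ~ Beta(7.76, 5.86) (mean 0.570, point estimate 0.58), and a bladder
#' void interval uniform on {4, 5, 6} hours. Gamma parameters are
#' (shape, rate); the (shape, scale) reading is inconsistent with the point
#' estimates by two orders of magnitude.
#'
#' @param half_life_shape,half_life_rate Gamma shape/rate for the
#'   elimination half-life in hours.
#' @param f_shape1,f_shape2 Beta parameters for the fraction of ingested
#'   lambda-cyhalothrin absorbed and metabolized to 3PBA.
#' @param V_shape,V_rate Gamma shape/rate for the volume of distribution (L).
#' @param R_shape1,R_shape2 Beta parameters for the fraction of urinary
#'   (3PBA + 4OH3PBA) excreted as 3PBA.
#' @param void_choices Integer vector of admissible bladder void intervals
#'   (hours), sampled with equal probability.
#' @return A list of class `pk_priors`.
#' @seealso [sample_pk_parameters()], [pk_point_estimates()]
#' @export
pk_priors <- function(half_life_shape = 24.2, half_life_rate = 3.79,
                      f_shape1 = 11.1, f_shape2 = 31.4,
                      V_shape = 6.78, V_rate = 0.38,
                      R_shape1 = 7.76, R_shape2 = 5.86,
                      void_choices = 4:6) {
  p <- list(half_life_shape = half_life_shape, half_life_rate = half_life_rate,
            f_shape1 = f_shape1, f_shape2 = f_shape2,
            V_shape = V_shape, V_rate = V_rate,
            R_shape1 = R_shape1, R_shape2 = R_shape2,
            void_choices = as.integer(void_choices))
  for (nm in setdiff(names(p), "void_choices")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("pk_priors: '", nm, "' must be a single positive finite number")
    }
  }
  if (length(p$void_choices) < 1L || any(p$void_choices < 1L)) {
    stop("pk_priors: 'void_choices' must be positive integers")
  }
  structure(p, class = "pk_priors")
}

#' Point estimates of the 3PBA pharmacokinetic parameters
#'
#' Deterministic parameter set used in point-estimate (non-Monte-Carlo) mode:
#' elimination rate k = 0.108 1/h, absorbed-and-metabolized fraction
#' f = 0.25, volume of distribution V = 17.7 L, 3PBA fraction of urinary
#' metabolite R = 0.58, void interval 5 h.
#'
#' @return One-row data frame with columns `k`, `f`, `V`, `R`,
#'   `void_interval`.
#' @export
pk_point_estimates <- function() {
  data.frame(k = 0.108, f = 0.25, V = 17.7, R = 0.58, void_interval = 5L)
}

#' Food-washing behavior parameters
#'
#' Each participant-iterate is independently assigned washer status by a
#' Bernoulli draw (default probability 0.5, the conservative low end of
#' survey-reported washing prevalence) and, for washers, a multiplicative
#' residue reduction drawn from a Beta distribution with mean 0.30
#' (default Beta(3, 7), wide support on \[0, 1\] reflecting the large
#' reported spread in washing effectiveness, roughly 18-90% reduction).
#'
#' @param washer_prob Probability a participant-iterate washes food.
#' @param washing_shape1,washing_shape2 Beta parameters of the washing
#'   reduction factor.
#' @return A list of class `behavior_config`.
#' @export
behavior_config <- function(washer_prob = 0.5,
                            washing_shape1 = 3, washing_shape2 = 7) {
  if (!is.numeric(washer_prob) || length(washer_prob) != 1L ||
      is.na(washer_prob) || washer_prob < 0 || washer_prob > 1) {
    stop("behavior_config: 'washer_prob' must be in [0, 1]")
  }
  if (washing_shape1 <= 0 || washing_shape2 <= 0) {
    stop("behavior_config: 'washing_shape1' and 'washing_shape2' must be positive")
  }
  structure(list(washer_prob = washer_prob,
                 washing_shape1 = washing_shape1,
                 washing_shape2 = washing_shape2),
            class = "behavior_config")
}

#' Constants of the creatinine excretion-rate formulas
#'
#' The urinary creatinine excretion rate N (mg/h) is predicted from body
#' weight, height, age, and sex with two branches:
#' \describe{
#'   \item{adult (age > `child_age_max`)}{Cockcroft-Gault-type power law
#'     `CER (mg/day) = K_sex * (140 - age) * weight^1.5 * sqrt(height)`
#'     with weight in kg and height in cm; default K is 1.93e-3 for males
#'     and 1.64e-3 for females (about 2040 mg/day for an 80 kg, 180 cm,
#'     30-year-old man).}
#'   \item{child (age <= `child_age_max`, default 18 y)}{per-kilogram rate
#'     `CER (mg/day) = c_sex * weight`, default 18 mg/kg/day for boys and
#'     16 mg/kg/day for girls.}
#' }
#' All constants are configuration, not hard-coded, so alternative published
#' formulas can be swapped in.
#'
#' @param adult_coef Named numeric, `c(male=, female=)`, adult coefficient
#'   K_sex of the power law (mg/day units).
#' @param child_per_kg Named numeric, `c(male=, female=)`, child excretion
#'   in mg creatinine per kg body weight per day.
#' @param child_age_max Age (years) at or below which the child branch is
#'   used.
#' @param age_max Maximum supported age; the adult formula's `(140 - age)`
#'   term must stay positive.
#' @return A list of class `creatinine_constants`.
#' @export
creatinine_constants <- function(adult_coef = c(male = 1.93e-3, female = 1.64e-3),
                                 child_per_kg = c(male = 18, female = 16),
                                 child_age_max = 18,
                                 age_max = 110) {
  if (!all(c("male", "female") %in% names(adult_coef)) ||
      !all(c("male", "female") %in% names(child_per_kg))) {
    stop("creatinine_constants: coefficients must be named 'male' and 'female'")
  }
  if (any(adult_coef <= 0) || any(child_per_kg <= 0)) {
    stop("creatinine_constants: all coefficients must be positive")
  }
  structure(list(adult_coef = adult_coef, child_per_kg = child_per_kg,
                 child_age_max = child_age_max, age_max = age_max),
            class = "creatinine_constants")
}

#' Configuration of the synthetic-data generator
#'
#' Defines the statistical conditions the generator emulates. The daily-dose
#' log-normal defaults are calibrated so the generated per-iterate exposure
#' distribution matches the reported regulatory dietary-exposure percentiles
#' for lambda-cyhalothrin (median 1.3e-4 and 95th percentile 3.4e-4
#' mg/kg/day): `meanlog = log(1.3e-4)`, `sdlog = log(3.4/1.3)/qnorm(0.95)`.
#' The biomarker limit of detection defaults to 0.1 ug/L with the LOD/sqrt(2)
#' substitution convention for censored values.
#'
#' @param n_participants Number of simulated survey participants.
#' @param n_iterates Monte Carlo exposure iterates per participant
#'   (default 5, the demonstration value).
#' @param seed Integer seed; every generator is deterministic given it.
#' @param daily_dose_logmean,daily_dose_logsd Natural-log-scale mean and sd
#'   of the per-iterate daily dose (mg/kg/day scale).
#' @param lod Limit of detection for urinary 3PBA (ug/L).
#' @param measurement_noise_logsd Log10-scale sd of the multiplicative
#'   measurement/model error applied when simulating measured biomarkers.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 100L,
                         n_iterates = 5L,
                         seed = 1L,
                         daily_dose_logmean = log(1.3e-4),
                         daily_dose_logsd = log(3.4 / 1.3) / stats::qnorm(0.95),
                         lod = 0.1,
                         measurement_noise_logsd = 0.5) {
  check_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
        x != as.integer(x)) {
      stop("synth_config: '", nm, "' must be a positive integer")
    }
    as.integer(x)
  }
  cfg <- list(n_participants = check_count(n_participants, "n_participants"),
              n_iterates = check_count(n_iterates, "n_iterates"),
              seed = check_count(seed, "seed"),
              daily_dose_logmean = daily_dose_logmean,
              daily_dose_logsd = daily_dose_logsd,
              lod = lod,
              measurement_noise_logsd = measurement_noise_logsd)
  if (!is.numeric(cfg$daily_dose_logmean) || !is.finite(cfg$daily_dose_logmean)) {
    stop("synth_config: 'daily_dose_logmean' must be finite")
  }
  if (!is.numeric(cfg$daily_dose_logsd) || cfg$daily_dose_logsd < 0) {
    stop("synth_config: 'daily_dose_logsd' must be >= 0")
  }
  if (!is.numeric(cfg$lod) || is.na(cfg$lod) || cfg$lod <= 0) {
    stop("synth_config: 'lod' must be > 0")
  }
  if (!is.numeric(cfg$measurement_noise_logsd) || cfg$measurement_noise_logsd < 0) {
    stop("synth_config: 'measurement_noise_logsd' must be >= 0")
  }
  structure(cfg, class = "synth_config")
}

#' Full pipeline configuration
#'
#' Bundles every tunable of the simulate -> predict -> ABC-filter ->
#' summarize pipeline. All defaults reproduce the published analysis
#' configuration: 5 Monte Carlo iterates, ABC thresholds c = 1.0 and 0.5
#' log10 units, washer probability 0.5 with washing reduction mean 0.30,
#' the Table-of-kinetics priors, LOD 0.1 ug/L, a prediction floor of 1e-12
#' ug/ug applied before log transforms, and MEC-style weights divided by
#' the 2 survey cycles.
#'
#' @param seed Global integer seed, expanded into fixed-offset per-stage
#'   seeds so stages can be rerun in isolation.
#' @param n_participants,n_iterates,daily_dose_logmean,daily_dose_logsd,lod,measurement_noise_logsd
#'   Passed to [synth_config()].
#' @param thresholds Numeric vector of ABC log10 thresholds.
#' @param floor Prediction floor (ug 3PBA per ug creatinine) applied before
#'   any log10 transform.
#' @param priors A [pk_priors()] object.
#' @param behavior A [behavior_config()] object.
#' @param creatinine A [creatinine_constants()] object.
#' @param point_estimates Logical; if TRUE the pharmacokinetic parameters
#'   are fixed at [pk_point_estimates()] instead of sampled.
#' @param n_cycles Number of pooled survey cycles; analysis weights are the
#'   exam weights divided by this.
#' @param probs Percentile levels for summary tables.
#' @return A list of class `pipeline_config`.
#' @seealso [run_pipeline()]
#' @export
pipeline_config <- function(seed = 1L,
                            n_participants = 500L,
                            n_iterates = 5L,
                            thresholds = c(1.0, 0.5),
                            floor = 1e-12,
                            lod = 0.1,
                            daily_dose_logmean = log(1.3e-4),
                            daily_dose_logsd = log(3.4 / 1.3) / stats::qnorm(0.95),
                            measurement_noise_logsd = 0.5,
                            priors = pk_priors(),
                            behavior = behavior_config(),
                            creatinine = creatinine_constants(),
                            point_estimates = FALSE,
                            n_cycles = 2L,
                            probs = c(0.5, 0.9, 0.95, 0.99)) {
  synth <- synth_config(n_participants = n_participants,
                        n_iterates = n_iterates, seed = seed,
                        daily_dose_logmean = daily_dose_logmean,
                        daily_dose_logsd = daily_dose_logsd,
                        lod = lod,
                        measurement_noise_logsd = measurement_noise_logsd)
  if (!is.numeric(thresholds) || length(thresholds) < 1L || any(thresholds <= 0)) {
    stop("pipeline_config: 'thresholds' must be positive")
  }
  if (!is.numeric(floor) || floor <= 0) {
    stop("pipeline_config: 'floor' must be > 0")
  }
  stopifnot(inherits(priors, "pk_priors"), inherits(behavior, "behavior_config"),
            inherits(creatinine, "creatinine_constants"))
  if (!is.numeric(n_cycles) || n_cycles < 1) {
    stop("pipeline_config: 'n_cycles' must be >= 1")
  }
  if (any(probs <= 0) || any(probs >= 1)) {
    stop("pipeline_config: 'probs' must lie in (0, 1)")
  }
  structure(list(seed = as.integer(seed), synth = synth,
                 thresholds = sort(thresholds, decreasing = TRUE),
                 floor = floor, priors = priors, behavior = behavior,
                 creatinine = creatinine,
                 point_estimates = isTRUE(point_estimates),
                 n_cycles = n_cycles, probs = probs),
            class = "pipeline_config")
}
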