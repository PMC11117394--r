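#' Sample pharmacokinetic parameters from their Monte Carlo priors
#'
#' Draws independent per-iterate parameter sets: elimination half-life from
#' its Gamma prior (then `k = ln(2) / half_life`), absorbed-and-metabolized
#' fraction `f` and 3PBA urinary fraction `R` from their Beta priors, volume
#' of distribution `V` from its Gamma prior, and the bladder void interval
#' uniformly from the admissible set. Non-finite or boundary draws are
#' rejected and redrawn (bounded retries). Uses the current R random number
#' stream; set a seed for reproducibility.
#'
#' @param n Number of parameter sets.
#' @param priors A [pk_priors()] object.
#' @param point_estimates If TRUE, return `n` copies of
#'   [pk_point_estimates()] instead of sampling.
#' @param max_retries Redraw attempts for degenerate draws.
#' @return Data frame with columns `k` (1/h), `f`, `V` (L), `R`,
#'   `void_interval` (h).
#' @export
sample_pk_parameters <- function(n, priors = pk_priors(),
                                 point_estimates = FALSE, max_retries = 100L) {
  n <- as.integer(n)
  if (point_estimates) {
    out <- pk_point_estimates()[rep(1L, n), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(priors, "pk_priors"))
  draw <- function() {
    half <- stats::rgamma(n, shape = priors$half_life_shape,
                          rate = priors$half_life_rate)
    data.frame(
      k = log(2) / half,
      f = stats::rbeta(n, priors$f_shape1, priors$f_shape2),
      V = stats::rgamma(n, shape = priors$V_shape, rate = priors$V_rate),
      R = stats::rbeta(n, priors$R_shape1, priors$R_shape2),
      void_interval = sample(priors$void_choices, n, replace = TRUE)
    )
  }
  out <- draw()
  bad <- function(p) {
    !is.finite(p$k) | p$k <= 0 | !is.finite(p$f) | p$f <= 0 | p$f >= 1 |
      !is.finite(p$V) | p$V <= 0 | !is.finite(p$R) | p$R <= 0 | p$R >= 1
  }
  tries <- 0L
  while (any(b <- bad(out))) {
    tries <- tries + 1L
    if (tries > max_retries) {
      stop("sample_pk_parameters: could not obtain finite draws")
    }
    repl <- draw()
    out[b, ] <- repl[b, , drop = FALSE]
  }
  out
}

#' Creatinine excretion rate from demographics and anthropometrics
#'
#' Predicts the urinary creatinine excretion rate N used to standardize
#' modelled urinary 3PBA, with distinct published-style power-law branches
#' for adults and children (age at most `constants$child_age_max`, default
#' 18 y); see [creatinine_constants()] for the formulas and defaults.
#' Vectorized over participants.
#'
#' @param age Years.
#' @param sex Character, "male" or "female".
#' @param weight Body weight (kg).
#' @param height Height (cm).
#' @param constants A [creatinine_constants()] object.
#' @param per Output units: `"hour"` (mg/h, default) or `"day"` (mg/day).
#' @return Positive excretion rate(s).
#' @export
creatinine_excretion_rate <- function(age, sex, weight, height,
                                      constants = creatinine_constants(),
                                      per = c("hour", "day")) {
  per <- match.arg(per)
  stopifnot(inherits(constants, "creatinine_constants"))
  if (!all(sex %in% c("male", "female"))) {
    stop("creatinine_excretion_rate: 'sex' must be \"male\" or \"female\"")
  }
  if (any(age < 0) || any(age > constants$age_max)) {
    stop("creatinine_excretion_rate: age outside the supported range [0, ",
         constants$age_max, "]")
  }
  if (any(weight <= 0) || any(height <= 0)) {
    stop("creatinine_excretion_rate: weight and height must be positive")
  }
  n <- max(length(age), length(sex), length(weight), length(height))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  weight <- rep_len(weight, n); height <- rep_len(height, n)
  child <- age <= constants$child_age_max
  per_day <- numeric(n)
  per_day[child] <- constants$child_per_kg[sex[child]] * weight[child]
  if (any(!child)) {
    a <- !child
    per_day[a] <- constants$adult_coef[sex[a]] * (140 - age[a]) *
      weight[a]^1.5 * sqrt(height[a])
  }
  if (any(per_day <= 0)) {
    stop("creatinine_excretion_rate: non-positive rate; check ages against the adult formula's range")
  }
  if (per == "hour") per_day / 24 else per_day
}

#' Serum 3PBA concentration series under piecewise-constant hourly dosing
#'
#' One-compartment kinetics with first-order elimination. Intake is
#' piecewise constant: the dose for hour t is ingested at a constant rate
#' over \[t, t+1). On that assumption the hourly update is exact:
#' \deqn{C_{t+1} = C_t e^{-k} + \frac{f D_t}{V k} (1 - e^{-k})}
#' with `D_t` the mg ingested during hour t, `f` the absorbed-and-
#' metabolized fraction, `V` the volume of distribution (L) and `k` the
#' elimination rate (1/h). There is no integration error at the hourly
#' grid points.
#'
#' @param params One-row data frame/list with `k`, `f`, `V`.
#' @param doses Numeric vector; `doses[i]` is the mg ingested during hour
#'   i-1 (i.e. hours 0, 1, ...). The final entry does not influence the
#'   returned series (the series ends at its left edge).
#' @param C0 Initial serum concentration at t = 0 (mg/L).
#' @return Numeric vector of serum concentrations (mg/L) at integer times
#'   0 .. length(doses), so one element longer than `doses`.
#' @export
serum_series <- function(params, doses, C0 = 0) {
  if (any(doses < 0)) stop("serum_series: doses must be non-negative")
  if (!is.numeric(C0) || length(C0) != 1L || C0 < 0) {
    stop("serum_series: 'C0' must be a single non-negative number")
  }
  k <- params$k; f <- params$f; V <- params$V
  stopifnot(k > 0, f > 0, V > 0)
  ek <- exp(-k)
  gain <- f / (V * k) * (1 - ek)
  Tn <- length(doses)
  C <- numeric(Tn + 1L)
  C[1L] <- C0
  for (t in seq_len(Tn)) C[t + 1L] <- C[t] * ek + doses[t] * gain
  C
}

#' Steady-state serum concentration under a constant intake rate
#'
#' Closed form of the one-compartment model's fixed point:
#' `C_ss = f * rate / (k * V)`. Used to initialize the serum series at
#' midnight of recall day 1 from the average pre-study intake rate.
#'
#' @param params One-row data frame/list with `k`, `f`, `V`.
#' @param hourly_rate Constant intake rate (mg/h), vectorized.
#' @return Steady-state concentration (mg/L); linear in `hourly_rate`.
#' @export
steady_state_concentration <- function(params, hourly_rate) {
  if (any(hourly_rate < 0)) {
    stop("steady_state_concentration: rate must be >= 0")
  }
  params$f * hourly_rate / (params$k * params$V)
}

#' Creatinine-standardized 3PBA concentration in urine entering the bladder
#'
#' The renal 3PBA mass flow is `k * V * C` mg/h (total metabolite cleared
#' from the compartment), of which fraction `R` appears in urine as 3PBA;
#' dividing by the creatinine excretion rate `N` (mg/h) gives a
#' dimensionless mg/mg = ug/ug concentration ratio:
#' `U = R * k * V * C / N`.
#'
#' @param params One-row data frame/list with `k`, `V`, `R`.
#' @param serum_value Serum 3PBA (mg/L); vectorized (e.g. a whole series).
#' @param N Creatinine excretion rate (mg/h).
#' @return Urinary 3PBA per urinary creatinine (ug/ug).
#' @export
urine_entering_bladder <- function(params, serum_value, N) {
  if (any(N <= 0)) stop("urine_entering_bladder: 'N' must be > 0")
  if (any(serum_value < 0)) {
    stop("urine_entering_bladder: serum values must be >= 0")
  }
  params$R * params$k * params$V * serum_value / N
}

#' Bladder-average urinary concentration at collection
#'
#' Urine accumulates in the bladder between voids, so the measured spot
#' concentration reflects a mixture of the urine produced since the last
#' void. This is modelled as the arithmetic mean of the hourly
#' entering-bladder concentrations over the `void_interval` hours ending
#' at the collection hour (window clipped at the start of the series).
#'
#' @param urine_in Numeric vector of entering-bladder concentrations at
#'   integer times 0 .. T (ug/ug).
#' @param collection_index Integer time index (hour since series start) of
#'   collection; the window ends here, inclusive.
#' @param void_interval Window length in hours (typically 4-6).
#' @return Mean concentration over the window (ug/ug).
#' @export
bladder_average <- function(urine_in, collection_index, void_interval) {
  collection_index <- as.integer(collection_index)
  void_interval <- as.integer(void_interval)
  if (void_interval < 1L) stop("bladder_average: 'void_interval' must be >= 1")
  if (collection_index < 0L || collection_index > length(urine_in) - 1L) {
    stop("bladder_average: 'collection_index' outside the series")
  }
  lo <- max(0L, collection_index - void_interval + 1L)
  mean(urine_in[(lo + 1L):(collection_index + 1L)])
}

#' Predict creatinine-standardized urinary 3PBA for one participant-iterate
#'
#' End-to-end composition of the forward model: steady-state initial serum
#' concentration from the pre-study intake rate, hourly serum series under
#' the ingestion schedule, conversion to the entering-bladder urinary
#' concentration, and bladder averaging over the void interval ending at
#' the collection hour.
#'
#' @param schedule A `dose_schedule` from [build_schedule()].
#' @param params One-row data frame with `k`, `f`, `V`, `R`,
#'   `void_interval`.
#' @param N Creatinine excretion rate (mg/h) for this participant.
#' @return Predicted urinary 3PBA per creatinine (ug/ug); zero exposure
#'   yields exactly 0 (any flooring happens downstream, before log
#'   transforms).
#' @export
predict_urinary_3pba <- function(schedule, params, N) {
  stopifnot(inherits(schedule, "dose_schedule"))
  C0 <- steady_state_concentration(params, schedule$initial_rate)
  Tn <- schedule$collection_index
  serum <- serum_series(params, schedule$doses[seq_len(Tn)], C0 = C0)
  urine <- urine_entering_bladder(params, serum, N)
  bladder_average(urine, Tn, params$void_interval)
}

#' Creatinine-standardize a measured urinary 3PBA concentration
#'
#' Converts a measured concentration pair (urinary 3PBA in ug/L, urinary
#' creatinine in mg/dL) to the model's ug 3PBA per ug creatinine scale:
#' 1 mg/dL = 1e4 ug/L, so the result is `urinary_3pba / (creatinine * 1e4)`.
#'
#' @param urinary_3pba Measured urinary 3PBA (ug/L); vectorized.
#' @param creatinine Urinary creatinine (mg/dL); must be positive.
#' @return Concentration ratio in ug/ug.
#' @export
standardize_measurement <- function(urinary_3pba, creatinine) {
  if (any(creatinine <= 0)) {
    stop("standardize_measurement: 'creatinine' must be > 0")
  }
  urinary_3pba / (creatinine * 1e4)
}
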