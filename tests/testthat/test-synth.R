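test_that("population generation is reproducible and satisfies its invariants", {
  cfg <- synth_config(n_participants = 500L, seed = 7L)
  pop1 <- generate_population(cfg)
  pop2 <- generate_population(cfg)
  expect_identical(pop1, pop2)

  expect_equal(nrow(pop1), 500L)
  expect_true(all(lengths(pop1$meal_hours) >= 1L))
  expect_true(all(lengths(pop1$meal_hours) <= 5L))
  expect_true(all(pop1$collection_hour >= 0 & pop1$collection_hour <= 23))
  expect_true(all(pop1$fasting_hours >= 0))
  expect_true(all(pop1$body_weight > 0))
  expect_true(all(pop1$height > 0))
  expect_true(all(pop1$survey_weight > 0))
  expect_setequal(unique(pop1$cycle), 1:2)
  # ages span children, adolescents, adults and seniors
  expect_true(any(pop1$age >= 6 & pop1$age <= 11))
  expect_true(any(pop1$age >= 12 & pop1$age <= 19))
  expect_true(any(pop1$age >= 20 & pop1$age <= 59))
  expect_true(any(pop1$age >= 60))

  one <- generate_population(synth_config(n_participants = 1L, seed = 7L))
  expect_equal(nrow(one), 1L)
  expect_gte(length(one$meal_hours[[1L]]), 1L)
})

test_that("invalid synthetic configuration fails naming the field", {
  expect_error(synth_config(n_participants = 0), "n_participants")
  expect_error(synth_config(lod = -1), "lod")
  expect_error(synth_config(measurement_noise_logsd = -0.1),
               "measurement_noise_logsd")
  expect_error(generate_population(list()), "synth_config")
})

test_that("exposure iterates follow the configured log-normal", {
  pop <- generate_population(synth_config(n_participants = 200L, seed = 3L))

  # degenerate spread: every dose equals exp(meanlog)
  cfg0 <- synth_config(n_participants = 200L, seed = 3L, daily_dose_logsd = 0)
  exp0 <- generate_exposure_iterates(pop, cfg0)
  expect_true(all(exp0$day1_dose == exp(cfg0$daily_dose_logmean)))
  expect_true(all(exp0$day2_dose == exp(cfg0$daily_dose_logmean)))

  # default 5 iterates per participant, all positive, day1/day2 independent
  cfg <- synth_config(n_participants = 200L, seed = 3L)
  ex <- generate_exposure_iterates(pop, cfg)
  expect_equal(unname(table(ex$participant_id)),
               rep(5L, 200L), ignore_attr = TRUE)
  expect_true(all(ex$day1_dose > 0))
  expect_false(any(ex$day1_dose == ex$day2_dose))

  # sample mean of log doses within 3 s.e. of the configured parameter
  lg <- log(c(ex$day1_dose, ex$day2_dose))
  se <- cfg$daily_dose_logsd / sqrt(length(lg))
  expect_lt(abs(mean(lg) - cfg$daily_dose_logmean), 3 * se)
})

test_that("noise-free measurements reproduce the forward prediction exactly", {
  cfg <- synth_config(n_participants = 50L, seed = 11L,
                      measurement_noise_logsd = 0, lod = 1e-30)
  pop <- generate_population(cfg)
  ex <- generate_exposure_iterates(pop, cfg)
  set.seed(99)
  tp <- sample_pk_parameters(nrow(pop))
  tb <- fixture_behavior(is_washer = rep(FALSE, nrow(pop)))
  meas <- simulate_measurements(pop, ex, tp, cfg, true_behavior = tb)
  pred <- predict_batch(pop, ex[ex$iterate == 1L, ], tp, tb)$predicted_ugug

  expect_false(any(meas$below_lod))
  expect_equal(standardize_measurement(meas$urinary_3pba, meas$creatinine),
               pred, tolerance = 1e-12)
})

test_that("LOD censoring matches its analytic probability", {
  # noiseless run with negligible LOD recovers the exact standardized
  # predictions and creatinine draws the censored run will reuse
  cfg0 <- synth_config(n_participants = 500L, seed = 21L,
                       measurement_noise_logsd = 0, lod = 1e-30)
  pop <- generate_population(cfg0)
  ex <- generate_exposure_iterates(pop, cfg0)
  set.seed(77)
  tp <- sample_pk_parameters(nrow(pop))
  tb <- fixture_behavior(is_washer = rep(FALSE, nrow(pop)))
  base <- simulate_measurements(pop, ex, tp, cfg0, true_behavior = tb)
  pred_ugL <- base$urinary_3pba  # noise-free ug/L values

  sigma <- 0.5
  cfg <- synth_config(n_participants = 500L, seed = 21L,
                      measurement_noise_logsd = sigma, lod = 0.1)
  noisy <- simulate_measurements(pop, ex, tp, cfg, true_behavior = tb)
  expect_equal(noisy$creatinine, base$creatinine)  # same per-stage stream

  p_cens <- pnorm((log10(cfg$lod) - log10(pred_ugL)) / sigma)
  se <- sqrt(sum(p_cens * (1 - p_cens))) / length(p_cens)
  expect_lt(abs(mean(noisy$below_lod) - mean(p_cens)), 3 * se + 1e-12)
  expect_true(all(noisy$urinary_3pba[noisy$below_lod] == cfg$lod / sqrt(2)))
})

test_that("censoring substitutes LOD/sqrt(2) for every sub-LOD value", {
  cfg <- synth_config(n_participants = 30L, seed = 5L, lod = 1e6)
  pop <- generate_population(cfg)
  ex <- generate_exposure_iterates(pop, cfg)
  set.seed(5)
  tp <- sample_pk_parameters(nrow(pop))
  meas <- simulate_measurements(pop, ex, tp, cfg)
  expect_true(all(meas$below_lod))
  expect_true(all(meas$urinary_3pba == cfg$lod / sqrt(2)))
})

test_that("a missing true iterate is an error", {
  cfg <- synth_config(n_participants = 10L, seed = 2L)
  pop <- generate_population(cfg)
  ex <- generate_exposure_iterates(pop, cfg)
  set.seed(1)
  tp <- sample_pk_parameters(nrow(pop))
  expect_error(
    simulate_measurements(pop, ex[ex$iterate != 1L, ], tp, cfg),
    "true iterate")
})

test_that("the single-bolus dosing study behaves like first-order washout", {
  fx <- generate_dosing_study_fixture(n_subjects = 6L, dose_mg_per_kg = 1e-3,
                                      sampling_hours = 0:120, seed = 42L)
  expect_equal(length(unique(fx$subject)), 6L)
  expect_true(all(fx$urinary_3pba_ugug >= 0))
  for (s in unique(fx$subject)) {
    conc <- fx$urinary_3pba_ugug[fx$subject == s]
    peak <- which.max(conc)
    expect_true(all(diff(conc[peak:length(conc)]) <= 1e-15))
  }

  fx2 <- generate_dosing_study_fixture(n_subjects = 6L, dose_mg_per_kg = 1e-3,
                                       sampling_hours = 0:120, seed = 42L)
  expect_identical(fx, fx2)

  zero <- generate_dosing_study_fixture(dose_mg_per_kg = 0, seed = 1L)
  expect_true(all(zero$urinary_3pba_ugug == 0))

  expect_error(generate_dosing_study_fixture(sampling_hours = c(0, 121)),
               "\\[0, 120\\]")
})
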