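test_that("sampled pharmacokinetic parameters match their prior moments", {
  set.seed(314)
  p <- sample_pk_parameters(1e5)
  # V ~ Gamma(6.78, rate 0.38): mean 17.84, sd 6.85
  expect_lt(abs(mean(p$V) - 6.78 / 0.38), 3 * (sqrt(6.78) / 0.38) / sqrt(1e5))
  # f ~ Beta(11.1, 31.4): mean 0.2612
  f_mean <- 11.1 / 42.5
  f_sd <- sqrt(11.1 * 31.4 / (42.5^2 * 43.5))
  expect_lt(abs(mean(p$f) - f_mean), 3 * f_sd / sqrt(1e5))
  # k = ln2 / half-life, half-life ~ Gamma(24.2, 3.79):
  # E[k] = ln2 * rate / (shape - 1), sd(k) = ln2 * rate / ((shape-1) sqrt(shape-2))
  k_mean <- log(2) * 3.79 / 23.2
  k_sd <- log(2) * 3.79 / (23.2 * sqrt(22.2))
  expect_lt(abs(mean(p$k) - k_mean), 3 * k_sd / sqrt(1e5))
  expect_setequal(unique(p$void_interval), 4:6)
  expect_true(all(p$k > 0 & p$f > 0 & p$f < 1 & p$V > 0 & p$R > 0 & p$R < 1))
})

test_that("point-estimate mode returns the published central values", {
  p <- sample_pk_parameters(3L, point_estimates = TRUE)
  expect_equal(nrow(p), 3L)
  expect_equal(p$k, rep(0.108, 3))
  expect_equal(p$f, rep(0.25, 3))
  expect_equal(p$V, rep(17.7, 3))
  expect_equal(p$R, rep(0.58, 3))
  expect_equal(p$void_interval, rep(5L, 3))
})

test_that("creatinine excretion follows the configured branch formulas", {
  cc <- creatinine_constants()
  # adult male, 80 kg, 180 cm, 30 y: hand evaluation of the power law
  by_hand <- 1.93e-3 * (140 - 30) * 80^1.5 * sqrt(180)
  expect_equal(creatinine_excretion_rate(30, "male", 80, 180, cc, per = "day"),
               by_hand)
  expect_equal(creatinine_excretion_rate(30, "male", 80, 180, cc, per = "hour"),
               by_hand / 24)
  # child branch engaged iff age <= 18
  r18 <- creatinine_excretion_rate(18, "female", 60, 165, cc, per = "day")
  r19 <- creatinine_excretion_rate(19, "female", 60, 165, cc, per = "day")
  expect_equal(r18, 16 * 60)
  expect_equal(r19, 1.64e-3 * (140 - 19) * 60^1.5 * sqrt(165))
  expect_error(creatinine_excretion_rate(30, "other", 80, 180), "sex")
  expect_error(creatinine_excretion_rate(150, "male", 80, 180), "age")
})

test_that("serum series reproduces closed-form decay and steady state", {
  p <- fixture_params()
  # pure decay from C0 = 1 over an empty schedule
  C <- serum_series(p, numeric(5L), C0 = 1)
  expect_equal(C[2L], exp(-0.108))
  expect_equal(C, exp(-0.108 * (0:5)))

  # constant rate converges to f*d/(k*V)
  d <- 0.5
  C2 <- serum_series(p, rep(d, 2000L), C0 = 0)
  css <- p$f * d / (p$k * p$V)
  expect_lt(abs(C2[2001L] - css) / css, 1e-6)
  expect_equal(steady_state_concentration(p, d), css)
  expect_equal(steady_state_concentration(p, 0), 0)
  expect_equal(steady_state_concentration(p, 2 * d), 2 * css)
  expect_equal(css, 0.25 * 0.5 / (0.108 * 17.7))

  expect_error(serum_series(p, c(1, -1)), "non-negative")
})

test_that("serum response is linear in the dose schedule (superposition)", {
  set.seed(9)
  p <- sample_pk_parameters(1L)
  A <- rexp(30L); B <- rexp(30L)
  expect_equal(serum_series(p, A + B, C0 = 0),
               serum_series(p, A, C0 = 0) + serum_series(p, B, C0 = 0),
               tolerance = 1e-12)
})

test_that("serum series matches an independent closed-form superposition", {
  set.seed(17)
  for (rep in 1:10) {
    p <- sample_pk_parameters(1L)
    doses <- rexp(36L) * rbinom(36L, 1L, 0.3)
    C0 <- runif(1, 0, 0.01)
    C <- serum_series(p, doses, C0 = C0)
    for (t_end in c(1L, 12L, 36L)) {
      expect_equal(C[t_end + 1L],
                   closed_form_serum(p$k, p$f, p$V, doses, C0, t_end),
                   tolerance = 1e-10)
    }
  }
})

test_that("urine entering the bladder scales serum by R*k*V/N", {
  p <- fixture_params()
  expect_equal(urine_entering_bladder(p, 0, N = 50), 0)
  expect_equal(urine_entering_bladder(p, 0.001, N = 50),
               0.58 * 0.108 * 17.7 * 0.001 / 50)
  expect_equal(urine_entering_bladder(p, 0.002, N = 50),
               2 * urine_entering_bladder(p, 0.001, N = 50))
  expect_error(urine_entering_bladder(p, 0.001, N = 0), "'N'")
})

test_that("bladder averaging is the mean over the void window", {
  u <- rep(3e-7, 20L)
  for (v in 4:6) expect_equal(bladder_average(u, 15L, v), 3e-7)

  u2 <- c(numeric(10L), c(2, 4, 6, 8) * 1e-7)
  expect_equal(bladder_average(u2, 13L, 4L), 5e-7)

  set.seed(4)
  u3 <- runif(30L)
  expect_equal(bladder_average(u3, 29L, 6L), mean(u3[25:30]))
  # window clipped at the series start
  expect_equal(bladder_average(u3, 2L, 6L), mean(u3[1:3]))
  expect_error(bladder_average(u3, 35L, 4L), "outside")
})

test_that("measured concentrations standardize to ug per ug creatinine", {
  expect_equal(standardize_measurement(0.39, 100), 3.9e-7)
  expect_equal(standardize_measurement(1, 1), 1e-4)
  expect_equal(standardize_measurement(2 * 0.39, 100),
               2 * standardize_measurement(0.39, 100))
  expect_error(standardize_measurement(1, 0), "creatinine")
})

test_that("end-to-end prediction matches a hand-expanded two-meal case", {
  ind <- fixture_individual(meal_hours = c(8L, 19L), collection_hour = 9L,
                            fasting_hours = 0.5, body_weight = 60)
  p <- fixture_params()
  s <- build_schedule(ind, 0.01, 0.005, fixture_behavior(FALSE))
  N <- creatinine_excretion_rate(ind$age, ind$sex, ind$body_weight, ind$height)
  got <- predict_urinary_3pba(s, p, N)

  # spreadsheet-style evaluation from first principles
  C0 <- p$f * s$initial_rate / (p$k * p$V)
  Tn <- s$collection_index
  serum <- vapply(0:Tn, function(t) {
    closed_form_serum(p$k, p$f, p$V, s$doses[seq_len(Tn)], C0, t)
  }, numeric(1L))
  urine <- p$R * p$k * p$V * serum / N
  expected <- mean(urine[(Tn - p$void_interval + 2L):(Tn + 1L)])
  expect_equal(got, expected, tolerance = 1e-10)

  # zero exposure predicts exactly zero
  s0 <- build_schedule(ind, 0, 0, fixture_behavior(FALSE))
  expect_equal(predict_urinary_3pba(s0, p, N), 0)
})

test_that("batch prediction equals the per-record composition", {
  cfg <- synth_config(n_participants = 25L, seed = 13L, n_iterates = 2L)
  pop <- generate_population(cfg)
  ex <- generate_exposure_iterates(pop, cfg)
  set.seed(13)
  params <- sample_pk_parameters(nrow(ex))
  behav <- sample_behavior(nrow(ex))
  batch <- predict_batch(pop, ex, params, behav)$predicted_ugug

  N <- creatinine_excretion_rate(pop$age, pop$sex, pop$body_weight, pop$height)
  for (r in seq_len(nrow(ex))) {
    i <- match(ex$participant_id[r], pop$participant_id)
    s <- build_schedule(pop[i, ], ex$day1_dose[r], ex$day2_dose[r],
                        behav[r, ], iterate = ex$iterate[r])
    expect_equal(batch[r], predict_urinary_3pba(s, params[r, ], N[i]),
                 tolerance = 1e-10)
  }
})
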