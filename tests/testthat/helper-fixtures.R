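# shared fixtures built in code

# one hand-specified adult with three meals, collected mid-morning on day 2
fixture_individual <- function(meal_hours = c(8L, 12L, 19L),
                               collection_hour = 10L,
                               fasting_hours = 2,
                               body_weight = 70) {
  list(participant_id = "P00001", age = 40, sex = "male",
       body_weight = body_weight, height = 175,
       meal_hours = list(meal_hours),
       collection_hour = collection_hour, fasting_hours = fasting_hours,
       survey_weight = 1000, stratum = 1L, psu = 1L, cycle = 1L)
}

fixture_params <- function() pk_point_estimates()

fixture_behavior <- function(is_washer = FALSE, washing_factor = 0.3) {
  data.frame(is_washer = is_washer, washing_factor = washing_factor)
}

# independent closed-form serum solution by superposition of the
# constant-rate building block (not the package's recursion)
closed_form_serum <- function(k, f, V, doses, C0, t_end) {
  ek1 <- 1 - exp(-k)
  C <- C0 * exp(-k * t_end)
  for (t in seq_along(doses)) {
    # dose during hour (t-1, t], fully elapsed by t_end when t <= t_end
    if (t <= t_end && doses[t] > 0) {
      C <- C + doses[t] * f / (V * k) * ek1 * exp(-k * (t_end - t))
    }
  }
  C
}

# prediction records with known log10 distances from measured = 1e-6
records_from_distances <- function(distances) {
  data.frame(
    participant_id = sprintf("P%03d", seq_along(distances)),
    iterate = 1L,
    measured = 1e-6,
    predicted = 1e-6 * 10^distances,
    stringsAsFactors = FALSE
  )
}
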