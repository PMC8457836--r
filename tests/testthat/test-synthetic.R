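test_that("ramp_setpoint follows the piecewise daily profile", {
  d <- assay_design()
  expect_equal(ramp_setpoint(d, 34.5, 0), 30.0)
  expect_equal(ramp_setpoint(d, 34.5, 1.5), 32.25)   # midpoint of 3 h ramp
  # cooling segment at 6.9 h, back to base at 7 h
  expect_equal(ramp_setpoint(d, 34.5, 6.9), 30 + 4.5 * 0.1)
  expect_equal(ramp_setpoint(d, 34.5, 7), 30.0)
  # hold phase and second-day cycle
  expect_equal(ramp_setpoint(d, 35, 4.5), 35)
  expect_equal(ramp_setpoint(d, 35, 24 + 4.5), 35)
  # after the last assay day the setpoint stays at base
  expect_equal(ramp_setpoint(d, 35, 48 + 4.5), 30)
  expect_error(ramp_setpoint(d, 33, 1), "valid targets")
  expect_error(assay_design(target_temps = numeric(0)), "non-empty")
  expect_error(assay_design(target_temps = 29), "exceed")
})

test_that("colony population simulation is seed-deterministic", {
  p <- population_params(seed = 11)
  a <- simulate_colony_population(p)
  b <- simulate_colony_population(p)
  expect_identical(a$colonies, b$colonies)
  c2 <- simulate_colony_population(population_params(seed = 12))
  expect_false(identical(a$colonies$control_load, c2$colonies$control_load))
})

test_that("noiseless population collapses to exact affine relations", {
  p <- population_params(retention_noise_sd = 0, growth_noise_sd = 0, seed = 3)
  cs <- simulate_colony_population(p)$colonies
  pred <- pmax(0, p$retention_intercept + p$retention_slope_per_load * cs$control_load)
  expect_equal(cs$retention, pred, tolerance = 1e-12)
  # OLS recovers the generating slope to machine precision
  fit <- ols_fit(cs$growth_pct, cs$control_load)
  expect_equal(unname(fit$coefficients[2, "estimate"]), p$growth_slope_per_load,
               tolerance = 1e-9)
  expect_equal(unname(fit$coefficients[1, "estimate"]), p$growth_intercept,
               tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("low-mode membership matches the mixture weight", {
  for (s in 1:5) {
    cs <- simulate_colony_population(population_params(seed = s))$colonies
    frac_low <- mean(cs$mixture_component == "low")
    expect_lt(abs(frac_low - 0.5), 0.1)  # binomial tolerance at n = 221
  }
})

test_that("population parameter validation catches bad inputs", {
  expect_error(population_params(n_colonies = 0), "integer >= 1")
  expect_error(population_params(load_mode_low = 0.3, load_mode_high = 0.2), "must be <")
  expect_error(population_params(retention_noise_sd = -1), "range")
})

test_that("cytometry simulator honours degenerate loads and determinism", {
  ev0 <- simulate_cytometry_sample(cytometry_sim_params(n_events = 1000, true_load = 0, seed = 4))
  expect_identical(attr(ev0, "truth")$n_symbiont, 0L)
  ev1 <- simulate_cytometry_sample(cytometry_sim_params(n_events = 1000, true_load = 1,
                                                        debris_fraction = 0, seed = 4))
  g <- gate_and_estimate_load(ev1, default_gating_for_sim())
  expect_equal(g$load, 1.0)
  a <- simulate_cytometry_sample(cytometry_sim_params(seed = 8))
  b <- simulate_cytometry_sample(cytometry_sim_params(seed = 8))
  expect_identical(a$fsc, b$fsc)
  expect_error(cytometry_sim_params(true_load = 1.2), "range")
  expect_error(cytometry_sim_params(symbiont_fluor_location = 1,
                                    coral_fluor_location = 2), "dominate")
})

test_that("temperature simulator injects exactly the promised exceedances", {
  sp <- spike_params(n_spikes = 5, spike_duration = 3, spike_amplitude = 4,
                     start = "2018-01-01", end = "2018-02-01", seed = 6)
  ts <- simulate_temperature_series(sp)
  # baseline + diurnal peaks at 29.8; spikes sit between 32.2 and 33.8
  expect_identical(count_exceedances(ts$series, 31), 15L)
  expect_identical(length(ts$spike_idx), 15L)
  # no spikes -> nothing above the diurnal envelope
  ts0 <- simulate_temperature_series(spike_params(n_spikes = 0))
  expect_identical(count_exceedances(ts0$series, 30), 0L)
  # determinism
  t2 <- simulate_temperature_series(sp)
  expect_identical(ts$series$temp_c, t2$series$temp_c)
  expect_identical(ts$spike_idx, t2$spike_idx)
  # impossible placement errors out
  expect_error(simulate_temperature_series(
    spike_params(n_spikes = 50, spike_duration = 200,
                 start = "2018-01-01", end = "2018-01-02")), "cannot place")
})

test_that("spikes never overlap across seeds", {
  for (s in 1:10) {
    sp <- spike_params(n_spikes = 20, spike_duration = 6,
                       start = "2018-01-01", end = "2018-03-01", seed = s)
    ts <- simulate_temperature_series(sp)
    expect_identical(length(ts$spike_idx), 120L)
    expect_identical(anyDuplicated(ts$spike_idx), 0L)
  }
})
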