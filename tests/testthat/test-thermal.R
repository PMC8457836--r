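mk_series <- function(temps, logger = "L1", reef = "R01", start = "2018-01-01") {
  data.frame(logger_id = rep(logger, length(temps)), reef_id = rep(reef, length(temps)),
             timestamp = as.POSIXct(start, tz = "UTC") + 600 * (seq_along(temps) - 1),
             temp_c = temps, stringsAsFactors = FALSE)
}

test_that("exceedance counting is strict and matches a loop oracle", {
  expect_identical(count_exceedances(mk_series(c(30, 32.1, 32, 33.5, 31.9)), 32), 2L)
  expect_identical(count_exceedances(mk_series(c(29, 30, 31)), 31.5), 0L)
  expect_error(count_exceedances(mk_series(numeric(0)), 32), "empty")
  set.seed(3)
  for (i in 1:20) {
    temps <- round(runif(sample(5:300, 1), 28, 35), 2)
    th <- runif(1, 29, 34)
    expect_identical(count_exceedances(mk_series(temps), th), exceed_oracle(temps, th))
  }
})

test_that("counts are monotone in threshold and additive over concatenation", {
  set.seed(4)
  for (i in 1:10) {
    a <- runif(100, 28, 35); b <- runif(80, 28, 35)
    expect_lte(count_exceedances(a, 33), count_exceedances(a, 32))
    expect_identical(count_exceedances(c(a, b), 32),
                     count_exceedances(a, 32) + count_exceedances(b, 32))
  }
})

test_that("reef summaries average over loggers, not pooled samples", {
  # logger A: 100 samples above 32; logger B: 128 above 32 (different lengths)
  a <- mk_series(c(rep(33, 100), rep(30, 50)), logger = "A")
  b <- mk_series(c(rep(33, 128), rep(30, 400)), logger = "B")
  s <- summarize_reef_thermal(list(a, b), thresholds = c(31, 32))
  expect_equal(unname(s$mean_exceedances["above_32"]), 114)
  expect_identical(s$n_loggers, 2L)
  single <- summarize_reef_thermal(list(a), thresholds = 32)
  expect_equal(unname(single$mean_exceedances), 100)
  expect_equal(single$coverage, 1)
  bad <- mk_series(rep(30, 5), logger = "C", reef = "R99")
  expect_error(summarize_reef_thermal(list(a, bad)), "mixed reef_ids")
})

test_that("per-year normalization divides by deployment length", {
  # 1 year of 10-min samples would be 52,596; use 1000 samples (~6.94 days)
  a <- mk_series(c(rep(33, 100), rep(30, 900)))
  raw <- summarize_reef_thermal(list(a), 32)
  ann <- summarize_reef_thermal(list(a), 32, per_year = TRUE)
  yrs <- (999 * 600) / (365.25 * 86400)
  expect_equal(unname(raw$mean_exceedances), 100)
  expect_equal(unname(ann$mean_exceedances), 100 / yrs, tolerance = 1e-9)
})

test_that("duplicate timestamps collapse with a warning; gaps lower coverage", {
  dup <- mk_series(rep(33, 10))
  dup <- rbind(dup, dup[5, ])
  dup <- dup[order(dup$timestamp), ]
  expect_warning(s <- summarize_reef_thermal(list(dup), 32), "duplicate timestamps")
  expect_equal(unname(s$mean_exceedances), 10)
  gappy <- mk_series(rep(33, 10))[-c(3, 4), ]
  s2 <- summarize_reef_thermal(list(gappy), 32)
  expect_lt(s2$coverage, 1)
})

test_that("simulated spike ground truth is recovered exactly across seeds", {
  for (s in 1:8) {
    k <- sample(1:10, 1); d <- sample(1:8, 1)
    sp <- spike_params(n_spikes = k, spike_duration = d, spike_amplitude = 5,
                       start = "2018-01-01", end = "2018-03-01", seed = s)
    ts <- simulate_temperature_series(sp)
    # threshold between the diurnal ceiling (29.8) and the spike floor (33.2)
    expect_identical(count_exceedances(ts$series, 31.5), k * d)
    expect_identical(count_exceedances(ts$series, 32.9), k * d)
  }
})

test_that("reef_thermal_table gives one row per reef", {
  ds <- simulate_dataset(pop = population_params(n_colonies = 8, n_reefs = 4),
                         cyto = cytometry_sim_params(n_events = 200),
                         spikes = spike_params(n_spikes = 3), seed = 5)
  tab <- reef_thermal_table(ds$loggers, thresholds = c(31, 32))
  expect_identical(nrow(tab), 4L)
  expect_true(all(c("above_31", "above_32") %in% names(tab)))
  expect_true(all(tab$above_32 <= tab$above_31))
})
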