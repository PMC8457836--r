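mk_events <- function(chl, fsc, id = "S1") {
  data.frame(sample_id = rep(id, length(chl)), fsc = fsc, chl_fluor = chl,
             stringsAsFactors = FALSE)
}
cfg <- gating_config(chl_threshold = 100, fsc_threshold = 50, min_cell_events = 1)

test_that("gating partitions events and computes the load as a cell fraction", {
  ev <- mk_events(chl = c(rep(200, 5), rep(10, 20)),
                  fsc = c(rep(60, 5), rep(60, 15), rep(10, 5)))
  g <- gate_and_estimate_load(ev, cfg)
  expect_identical(g$n_symbiont, 5L)
  expect_identical(g$n_coral, 15L)
  expect_identical(g$n_debris, 5L)
  expect_equal(g$load, 5 / 20)  # debris excluded from the denominator
  # "events" denominator mode divides by everything instead
  cfg_ev <- gating_config(100, 50, 1, load_denominator = "events")
  expect_equal(gate_and_estimate_load(ev, cfg_ev)$load, 5 / 25)
  # all symbionts
  expect_equal(gate_and_estimate_load(mk_events(rep(500, 9), rep(60, 9)), cfg)$load, 1)
})

test_that("threshold boundaries are strict and match a per-event loop oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    # values placed on a coarse grid so exact threshold hits occur often
    ev <- mk_events(chl = sample(c(50, 100, 150, 200), n, replace = TRUE),
                    fsc = sample(c(25, 50, 75), n, replace = TRUE))
    g <- gate_and_estimate_load(ev, cfg)
    o <- gate_oracle(ev, 100, 50)
    expect_identical(g$n_symbiont, o$n_symbiont)
    expect_identical(g$n_coral, o$n_coral)
    expect_identical(g$n_debris, o$n_debris)
    expect_equal(g$load, o$load)
  }
  # exactly at threshold -> not a symbiont
  g <- gate_and_estimate_load(mk_events(c(100, 100.0001), c(60, 60)), cfg)
  expect_identical(g$n_symbiont, 1L)
})

test_that("partition property and threshold monotonicity hold on random tables", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    ev <- mk_events(chl = rlnorm(n, 4, 2), fsc = rlnorm(n, 4, 1))
    g <- gate_and_estimate_load(ev, cfg)
    expect_identical(g$n_symbiont + g$n_coral + g$n_debris, n)
    expect_gte(g$load, 0); expect_lte(g$load, 1)
    g_hi <- gate_and_estimate_load(ev, gating_config(200, 50, 1))
    expect_lte(g_hi$n_symbiont, g$n_symbiont)
  }
})

test_that("gating errors and QC behave as specified", {
  expect_error(gate_and_estimate_load(mk_events(numeric(0), numeric(0)), cfg), "non-empty")
  expect_error(gate_and_estimate_load(mk_events(c(-1, 5), c(1, 1)), cfg), "negative")
  strict <- gating_config(100, 50, min_cell_events = 10)
  expect_error(gate_and_estimate_load(mk_events(rep(10, 12), rep(10, 12)), strict),
               "QC failure.*S1")
})

test_that("replicate aggregation: mean, cv, and QC flags", {
  g <- function(load) structure(list(sample_id = "S1", n_symbiont = 1L, n_coral = 9L,
                                     n_debris = 0L, load = load, qc_pass = TRUE),
                                class = "gated_counts")
  agg <- aggregate_replicates(list(g(0.10), g(0.12), g(0.14)), cfg)
  expect_equal(agg$mean_load, 0.12)
  expect_equal(agg$cv, 0.02 / 0.12, tolerance = 1e-12)
  expect_true(agg$qc_pass)
  one <- aggregate_replicates(list(g(0.1)), cfg)
  expect_equal(one$mean_load, 0.1)
  expect_true(is.na(one$cv))
  expect_true("single_replicate" %in% one$flags)
  expect_equal(aggregate_replicates(list(g(0.1), g(0.1), g(0.1)), cfg)$cv, 0)
  # high dispersion across replicates fails QC
  noisy <- aggregate_replicates(list(g(0.02), g(0.3), g(0.01)), cfg)
  expect_false(noisy$qc_pass)
  g2 <- g(0.1); g2$sample_id <- "S2"
  expect_error(aggregate_replicates(list(g(0.1), g2), cfg), "mix sample_ids")
  expect_error(aggregate_replicates(list(), cfg), "no replicates")
})

test_that("gating recovers the simulated true load", {
  errs <- vapply(1:10, function(s) {
    ev <- simulate_cytometry_sample(cytometry_sim_params(n_events = 5000,
                                                         true_load = 0.12, seed = s))
    gate_and_estimate_load(ev, default_gating_for_sim())$load -
      attr(ev, "truth")$n_symbiont / (attr(ev, "truth")$n_symbiont + attr(ev, "truth")$n_coral)
  }, 0)
  # against the realized composition misclassification is essentially nil
  expect_lt(max(abs(errs)), 0.005)
})
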