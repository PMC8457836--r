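#' Parameters for the colony-population simulator
#'
#' The simulated world mirrors the phenotype structure observed in the Palau
#' survey: control-nubbin symbiont load is drawn from a two-component Beta
#' mixture (a low mode near 5-6% and a high mode near 11-20% symbiont cells
#' per counted coral cell); heat-stress retention is weakly negatively
#' coupled to load; annual percent growth is weakly positively coupled to
#' load. Default effect sizes are tuned to the reported regime: load-
#' retention R-squared near 0.086 and load-growth R-squared near 0.026 at
#' n = 221 colonies.
#'
#' Mixture components are Beta densities re-parameterized by mode `m` and a
#' concentration (dispersion) parameter `c`: shape1 = 1 + m*c,
#' shape2 = 1 + (1-m)*c, so the density mode sits exactly at `m` and larger
#' `c` means tighter components.
#'
#' @param n_colonies number of colonies.
#' @param mix_weight_low probability a colony belongs to the low-load mode.
#' @param load_mode_low,load_mode_high component modes, fractions in (0,1)
#'   with `load_mode_low < load_mode_high`.
#' @param load_dispersion Beta concentration parameter (shared by both
#'   components); larger is tighter.
#' @param retention_intercept,retention_slope_per_load linear model for
#'   expected retention given load; the slope is negative by default.
#' @param retention_noise_sd Gaussian noise sd on retention; draws are
#'   truncated below at 0 but not capped at 1 (observed colonies can exceed
#'   retention 1).
#' @param growth_intercept,growth_slope_per_load,growth_noise_sd same for
#'   annual percent growth (% per year).
#' @param n_reefs number of reefs; colonies are assigned round-robin.
#' @param seed integer seed; identical seeds give identical tables.
#' @return an object of class `population_params`.
#' @export
population_params <- function(n_colonies = 221,
                              mix_weight_low = 0.5,
                              load_mode_low = 0.055,
                              load_mode_high = 0.15,
                              load_dispersion = 150,
                              retention_intercept = 0.95,
                              retention_slope_per_load = -4,
                              retention_noise_sd = 0.66,
                              growth_intercept = 4.6,
                              growth_slope_per_load = 12.5,
                              growth_noise_sd = 4.3,
                              n_reefs = 37,
                              seed = 1L) {
  check_count(n_colonies, "n_colonies")
  check_number(mix_weight_low, "mix_weight_low", 0, 1)
  check_number(load_mode_low, "load_mode_low", 0, 1, strict = TRUE)
  check_number(load_mode_high, "load_mode_high", 0, 1, strict = TRUE)
  if (load_mode_low >= load_mode_high)
    stop_("'load_mode_low' must be < 'load_mode_high'")
  check_number(load_dispersion, "load_dispersion", 0, strict = TRUE)
  check_number(retention_noise_sd, "retention_noise_sd", 0)
  check_number(growth_noise_sd, "growth_noise_sd", 0)
  check_count(n_reefs, "n_reefs")
  structure(list(
    n_colonies = as.integer(n_colonies), mix_weight_low = mix_weight_low,
    load_mode_low = load_mode_low, load_mode_high = load_mode_high,
    load_dispersion = load_dispersion,
    retention_intercept = retention_intercept,
    retention_slope_per_load = retention_slope_per_load,
    retention_noise_sd = retention_noise_sd,
    growth_intercept = growth_intercept,
    growth_slope_per_load = growth_slope_per_load,
    growth_noise_sd = growth_noise_sd,
    n_reefs = as.integer(n_reefs), seed = as.integer(seed)
  ), class = "population_params")
}

beta_shapes_from_mode <- function(mode, concentration) {
  c(shape1 = 1 + mode * concentration, shape2 = 1 + (1 - mode) * concentration)
}

#' Simulate a colony phenotype population
#'
#' Draws a per-colony table with reef/region metadata, control symbiont
#' load, heat-stress retention, annual growth, and colony diameters, with
#' the generating parameters returned alongside as ground truth for
#' recovery tests.
#'
#' Retention noise is additive Gaussian truncated at 0 and deliberately not
#' capped at 1 (slightly "super-retaining" colonies occur in real assays);
#' growth noise is untruncated. Reefs are laid out on a jittered grid of
#' Palau-like coordinates and assigned to the four compass regions
#' round-robin; half are labelled patch, half fore reefs.
#'
#' @param params a [population_params()] object.
#' @return a list of class `colony_sim` with elements `colonies` (data
#'   frame, one row per colony) and `truth` (the parameter list).
#' @export
simulate_colony_population <- function(params = population_params()) {
  stopifnot(inherits(params, "population_params"))
  p <- params
  n <- p$n_colonies
  with_seed(p$seed, {
    reef_id <- sprintf("R%02d", (seq_len(n) - 1L) %% p$n_reefs + 1L)
    reef_no <- (seq_len(n) - 1L) %% p$n_reefs + 1L
    regions <- c("North", "West", "East", "South")
    reef_region <- regions[(seq_len(p$n_reefs) - 1L) %% 4L + 1L]
    reef_type <- rep(c("patch", "fore"), length.out = p$n_reefs)
    # jittered Palau-like reef coordinates
    reef_lat <- 7.0 + 0.55 * ((seq_len(p$n_reefs) - 1) %% 7) / 6 + runif(p$n_reefs, -0.02, 0.02)
    reef_lon <- 134.2 + 0.45 * ((seq_len(p$n_reefs) - 1) %/% 7) / 5 + runif(p$n_reefs, -0.02, 0.02)

    low <- runif(n) < p$mix_weight_low
    sh_lo <- beta_shapes_from_mode(p$load_mode_low, p$load_dispersion)
    sh_hi <- beta_shapes_from_mode(p$load_mode_high, p$load_dispersion)
    load <- ifelse(low,
                   rbeta(n, sh_lo[1], sh_lo[2]),
                   rbeta(n, sh_hi[1], sh_hi[2]))
    retention <- pmax(0, p$retention_intercept + p$retention_slope_per_load * load +
                        if (p$retention_noise_sd > 0) rnorm(n, 0, p$retention_noise_sd) else 0)
    growth_pct <- p$growth_intercept + p$growth_slope_per_load * load +
      if (p$growth_noise_sd > 0) rnorm(n, 0, p$growth_noise_sd) else 0
    diameter_2018 <- exp(rnorm(n, log(30), 0.35))
    interval_days <- round(runif(n, 350, 380))
    diameter_2019 <- diameter_2018 * (1 + growth_pct / 100)
    colonies <- data.frame(
      colony_id = sprintf("C%03d", seq_len(n)),
      reef_id = reef_id,
      region = reef_region[reef_no],
      reef_type = reef_type[reef_no],
      depth_m = round(runif(n, 0.5, 1.6), 2),
      lat = reef_lat[reef_no],
      lon = reef_lon[reef_no],
      control_load = load,
      retention = retention,
      heated_load = load * retention,
      growth_pct = growth_pct,
      diameter_2018_cm = diameter_2018,
      diameter_2019_cm = diameter_2019,
      interval_days = interval_days,
      mixture_component = ifelse(low, "low", "high"),
      stringsAsFactors = FALSE
    )
  })
  structure(list(colonies = colonies, truth = unclass(p)), class = "colony_sim")
}
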