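#' Parameters for the cytometry event simulator
#'
#' Emulates the event cloud a small flow cytometer records from homogenized
#' coral tissue: symbiont-containing cells (high chlorophyll red
#' fluorescence), symbiont-free coral cells (low fluorescence, large forward
#' scatter) and debris (low fluorescence, small scatter). Channels are
#' log-normal in arbitrary units -- real instruments report arbitrary
#' intensity scales, so gating thresholds are configuration, not constants.
#'
#' Defaults separate the symbiont and coral fluorescence populations by ~4.6
#' log-units with sd 0.5, comfortably more than the gating threshold needs.
#'
#' @param n_events number of events to draw.
#' @param true_load fraction of cells (not events) that are
#'   symbiont-containing, in `[0, 1]`.
#' @param debris_fraction fraction of events that are debris, in `[0, 1)`.
#' @param symbiont_fluor_location,symbiont_fluor_scale log-space parameters
#'   of symbiont chlorophyll fluorescence.
#' @param coral_fluor_location,coral_fluor_scale same for symbiont-free cell
#'   (and debris) fluorescence; must sit well below the symbiont population.
#' @param fsc_cell_location,fsc_cell_scale log-space forward scatter of cells.
#' @param fsc_debris_location,fsc_debris_scale log-space forward scatter of
#'   debris.
#' @param seed integer seed.
#' @return object of class `cytometry_sim_params`.
#' @export
cytometry_sim_params <- function(n_events = 5000,
                                 true_load = 0.12,
                                 debris_fraction = 0.3,
                                 symbiont_fluor_location = log(1000),
                                 symbiont_fluor_scale = 0.5,
                                 coral_fluor_location = log(10),
                                 coral_fluor_scale = 0.5,
                                 fsc_cell_location = log(500),
                                 fsc_cell_scale = 0.4,
                                 fsc_debris_location = log(50),
                                 fsc_debris_scale = 0.4,
                                 seed = 1L) {
  check_count(n_events, "n_events")
  check_number(true_load, "true_load", 0, 1)
  check_number(debris_fraction, "debris_fraction", 0, 1)
  if (debris_fraction >= 1) stop_("'debris_fraction' must be < 1")
  check_number(symbiont_fluor_scale, "symbiont_fluor_scale", 0, strict = TRUE)
  check_number(coral_fluor_scale, "coral_fluor_scale", 0, strict = TRUE)
  if (symbiont_fluor_location <= coral_fluor_location)
    stop_("symbiont fluorescence must stochastically dominate coral-cell fluorescence")
  structure(list(
    n_events = as.integer(n_events), true_load = true_load,
    debris_fraction = debris_fraction,
    symbiont_fluor_location = symbiont_fluor_location,
    symbiont_fluor_scale = symbiont_fluor_scale,
    coral_fluor_location = coral_fluor_location,
    coral_fluor_scale = coral_fluor_scale,
    fsc_cell_location = fsc_cell_location, fsc_cell_scale = fsc_cell_scale,
    fsc_debris_location = fsc_debris_location, fsc_debris_scale = fsc_debris_scale,
    seed = as.integer(seed)
  ), class = "cytometry_sim_params")
}

#' Simulate one cytometry sample replicate
#'
#' Draws an event table with columns `fsc` and `chl_fluor`. Events are first
#' split debris vs. cells by `debris_fraction`; cells are symbiont-containing
#' with probability `true_load`. The realized per-class counts are returned
#' as the `truth` attribute for recovery tests.
#'
#' @param params a [cytometry_sim_params()] object.
#' @param sample_id identifier stored in the output table.
#' @return data frame (`sample_id`, `fsc`, `chl_fluor`) with attribute
#'   `truth` = list(n_symbiont, n_coral, n_debris, true_load).
#' @export
simulate_cytometry_sample <- function(params = cytometry_sim_params(),
                                      sample_id = "S1") {
  stopifnot(inherits(params, "cytometry_sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_events
    is_debris <- runif(n) < p$debris_fraction
    is_symb <- !is_debris & (runif(n) < p$true_load)
    fsc <- numeric(n); chl <- numeric(n)
    nc <- sum(!is_debris); nd <- sum(is_debris); ns <- sum(is_symb)
    fsc[!is_debris] <- rlnorm(nc, p$fsc_cell_location, p$fsc_cell_scale)
    fsc[is_debris] <- rlnorm(nd, p$fsc_debris_location, p$fsc_debris_scale)
    chl[is_symb] <- rlnorm(ns, p$symbiont_fluor_location, p$symbiont_fluor_scale)
    chl[!is_symb] <- rlnorm(n - ns, p$coral_fluor_location, p$coral_fluor_scale)
    events <- data.frame(sample_id = sample_id, fsc = fsc, chl_fluor = chl,
                         stringsAsFactors = FALSE)
  })
  attr(events, "truth") <- list(n_symbiont = sum(is_symb),
                                n_coral = sum(!is_debris & !is_symb),
                                n_debris = sum(is_debris),
                                true_load = p$true_load)
  events
}

#' Default gating thresholds matched to the simulator
#'
#' Thresholds at the log-scale midpoints between the simulated population
#' locations. For real instrument data thresholds are mandatory
#' configuration, since gating protocols are instrument-specific.
#'
#' @param params a [cytometry_sim_params()] object.
#' @return a [gating_config()] object.
#' @export
default_gating_for_sim <- function(params = cytometry_sim_params()) {
  gating_config(
    chl_threshold = exp((params$symbiont_fluor_location + params$coral_fluor_location) / 2),
    fsc_threshold = exp((params$fsc_cell_location + params$fsc_debris_location) / 2)
  )
}
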