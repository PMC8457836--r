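#' Gating configuration
#'
#' Thresholds and QC limits used to classify cytometry events. An event is a
#' symbiont-containing cell when `chl_fluor > chl_threshold` (strict); of the
#' remainder, events with `fsc > fsc_threshold` (strict) are symbiont-free
#' coral cells; everything else is debris. Strict boundaries make the
#' partition deterministic.
#'
#' @param chl_threshold chlorophyll fluorescence threshold (> 0), instrument
#'   units.
#' @param fsc_threshold forward-scatter threshold (> 0), instrument units.
#' @param min_cell_events QC: minimum symbiont + coral cells per replicate.
#' @param max_replicate_cv QC: maximum coefficient of variation across
#'   replicate loads of a sample.
#' @param load_denominator `"cells"` (default; debris excluded from the
#'   denominator) or `"events"` (load = symbiont cells / all events; exposed
#'   for sensitivity analysis, not endorsed).
#' @return object of class `gating_config`.
#' @export
gating_config <- function(chl_threshold, fsc_threshold,
                          min_cell_events = 100,
                          max_replicate_cv = 0.5,
                          load_denominator = c("cells", "events")) {
  check_number(chl_threshold, "chl_threshold", 0, strict = TRUE)
  check_number(fsc_threshold, "fsc_threshold", 0, strict = TRUE)
  min_cell_events <- check_count(min_cell_events, "min_cell_events", min = 1L)
  check_number(max_replicate_cv, "max_replicate_cv", 0)
  structure(list(chl_threshold = chl_threshold, fsc_threshold = fsc_threshold,
                 min_cell_events = min_cell_events,
                 max_replicate_cv = max_replicate_cv,
                 load_denominator = match.arg(load_denominator)),
            class = "gating_config")
}

#' Gate one event table and estimate symbiont load
#'
#' Partitions every event into exactly one of symbiont cell / coral cell /
#' debris and computes the symbiont load as symbiont-containing cells divided
#' by the total cell count (debris excluded; see `load_denominator`).
#'
#' @param events data frame with numeric columns `fsc` and `chl_fluor`
#'   (non-negative), optionally `sample_id`.
#' @param config a [gating_config()].
#' @return object of class `gated_counts`: `sample_id`, `n_symbiont`,
#'   `n_coral`, `n_debris`, `load`, `qc_pass`.
#' @examples
#' ev <- simulate_cytometry_sample(cytometry_sim_params(n_events = 2000, seed = 7))
#' gate_and_estimate_load(ev, default_gating_for_sim())
#' @export
gate_and_estimate_load <- function(events, config) {
  stopifnot(inherits(config, "gating_config"))
  if (!is.data.frame(events) || nrow(events) == 0L)
    stop_("'events' must be a non-empty data frame")
  if (!all(c("fsc", "chl_fluor") %in% names(events)))
    stop_("'events' needs columns 'fsc' and 'chl_fluor'")
  if (any(events$fsc < 0, na.rm = TRUE) || any(events$chl_fluor < 0, na.rm = TRUE))
    stop_("negative channel values")
  sid <- if ("sample_id" %in% names(events)) as.character(events$sample_id[1]) else NA_character_
  symb <- events$chl_fluor > config$chl_threshold
  coral <- !symb & events$fsc > config$fsc_threshold
  n_symbiont <- sum(symb)
  n_coral <- sum(coral)
  n_debris <- nrow(events) - n_symbiont - n_coral
  n_cells <- n_symbiont + n_coral
  if (n_cells < config$min_cell_events)
    stop_(sprintf("QC failure for sample '%s': only %d cell events (< %d)",
                  sid, n_cells, config$min_cell_events))
  load <- if (config$load_denominator == "cells") {
    n_symbiont / n_cells
  } else {
    n_symbiont / nrow(events)
  }
  structure(list(sample_id = sid, n_symbiont = n_symbiont, n_coral = n_coral,
                 n_debris = n_debris, load = load, qc_pass = TRUE),
            class = "gated_counts")
}

#' Aggregate replicate loads of one sample
#'
#' The per-sample load is the unweighted mean of replicate loads; the CV is
#' the sample sd divided by the mean (undefined for a single replicate, which
#' is flagged). QC fails when the CV exceeds `max_replicate_cv`.
#'
#' @param counts list of [gate_and_estimate_load()] results from the same
#'   sample.
#' @param config a [gating_config()].
#' @return object of class `replicate_summary`: `sample_id`, `mean_load`,
#'   `cv`, `n_replicates`, `qc_pass`, `flags`.
#' @export
aggregate_replicates <- function(counts, config) {
  stopifnot(inherits(config, "gating_config"))
  if (inherits(counts, "gated_counts")) counts <- list(counts)
  if (length(counts) == 0L) stop_("no replicates supplied")
  if (!all(vapply(counts, inherits, TRUE, "gated_counts")))
    stop_("'counts' must be gated_counts objects")
  sids <- unique(vapply(counts, `[[`, "", "sample_id"))
  if (length(sids) > 1L)
    stop_("replicates mix sample_ids: ", paste(sids, collapse = ", "))
  loads <- vapply(counts, `[[`, 0, "load")
  mean_load <- mean(loads)
  flags <- character(0)
  cv <- NA_real_
  qc <- all(vapply(counts, `[[`, TRUE, "qc_pass"))
  if (length(loads) >= 2L) {
    cv <- if (mean_load > 0) sd(loads) / mean_load else NA_real_
    if (is.finite(cv) && cv > config$max_replicate_cv) {
      qc <- FALSE
      flags <- c(flags, "high_replicate_cv")
    }
  } else {
    flags <- c(flags, "single_replicate")
  }
  structure(list(sample_id = sids, mean_load = mean_load, cv = cv,
                 n_replicates = length(loads), qc_pass = qc, flags = flags),
            class = "replicate_summary")
}
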