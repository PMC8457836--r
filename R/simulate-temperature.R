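#' Parameters for the temperature-logger simulator
#'
#' Emulates a moored reef logger sampling every 10 minutes over a deployment
#' window: a sinusoidal diurnal cycle around a baseline, plus injected warm
#' spikes of fixed amplitude and duration at non-overlapping random
#' positions. When the spike amplitude is large enough that baseline plus
#' diurnal cycle never crosses a threshold but every spiked sample does, the
#' exceedance count at that threshold is exactly
#' `n_spikes * spike_duration` by construction.
#'
#' @param baseline_temp mean water temperature, degC.
#' @param diurnal_amplitude half-range of the daily cycle, degC.
#' @param sample_interval_min sampling interval, minutes (default 10).
#' @param n_spikes number of injected warm events.
#' @param spike_amplitude added temperature during a spike, degC.
#' @param spike_duration spike length in samples.
#' @param start,end deployment window (coerced with [as.POSIXct()], UTC).
#' @param seed integer seed (spike placement).
#' @return object of class `spike_params`.
#' @export
spike_params <- function(baseline_temp = 29.0,
                         diurnal_amplitude = 0.8,
                         sample_interval_min = 10,
                         n_spikes = 24,
                         spike_amplitude = 4.5,
                         spike_duration = 6,
                         start = "2017-11-01",
                         end = "2018-07-01",
                         seed = 1L) {
  check_number(baseline_temp, "baseline_temp", 0, 40)
  check_number(diurnal_amplitude, "diurnal_amplitude", 0)
  check_number(sample_interval_min, "sample_interval_min", 0, strict = TRUE)
  n_spikes <- check_count(n_spikes, "n_spikes", min = 0L)
  check_number(spike_amplitude, "spike_amplitude", 0)
  spike_duration <- check_count(spike_duration, "spike_duration", min = 1L)
  start <- as.POSIXct(start, tz = "UTC"); end <- as.POSIXct(end, tz = "UTC")
  if (!(end > start)) stop_("'end' must be after 'start'")
  structure(list(baseline_temp = baseline_temp,
                 diurnal_amplitude = diurnal_amplitude,
                 sample_interval_min = sample_interval_min,
                 n_spikes = n_spikes, spike_amplitude = spike_amplitude,
                 spike_duration = spike_duration,
                 start = start, end = end, seed = as.integer(seed)),
            class = "spike_params")
}

#' Simulate a 10-minute temperature-logger series
#'
#' @param params a [spike_params()] object.
#' @param logger_id,reef_id identifiers stored in the output.
#' @return list of class `temperature_sim`: `series` (data frame with
#'   `logger_id`, `reef_id`, `timestamp`, `temp_c`) and `spike_idx` (integer
#'   sample indices belonging to spikes -- the ground truth).
#' @export
simulate_temperature_series <- function(params = spike_params(),
                                        logger_id = "L1", reef_id = "R01") {
  stopifnot(inherits(params, "spike_params"))
  p <- params
  step <- p$sample_interval_min * 60
  ts <- seq(from = p$start, to = p$end, by = step)
  n <- length(ts)
  hours <- as.numeric(ts - ts[1], units = "hours")
  temp <- p$baseline_temp + p$diurnal_amplitude * sin(2 * pi * (hours - 8) / 24)
  spike_idx <- integer(0)
  if (p$n_spikes > 0) {
    need <- p$n_spikes * (p$spike_duration + 1L)  # +1 gap to keep spikes apart
    if (need > n)
      stop_(sprintf("cannot place %d non-overlapping spikes of %d samples in %d samples",
                    p$n_spikes, p$spike_duration, n))
    spike_starts <- with_seed(p$seed, {
      # distinct sorted anchors, shifted so consecutive spikes cannot overlap
      cuts <- sort(sample.int(n - p$n_spikes * p$spike_duration + 1L, p$n_spikes))
      cuts + (seq_len(p$n_spikes) - 1L) * p$spike_duration
    })
    spike_idx <- as.integer(outer(seq_len(p$spike_duration) - 1L, spike_starts, `+`))
    spike_idx <- sort(spike_idx)
    temp[spike_idx] <- temp[spike_idx] + p$spike_amplitude
  }
  series <- data.frame(logger_id = logger_id, reef_id = reef_id,
                       timestamp = ts, temp_c = temp, stringsAsFactors = FALSE)
  structure(list(series = series, spike_idx = spike_idx), class = "temperature_sim")
}
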