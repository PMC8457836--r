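#' Standardized heat-stress assay design
#'
#' Describes the temperature protocol of the 2-day standardized bleaching
#' assay: nubbins are ramped from ambient to a target temperature, held, and
#' cooled back, once per day. Defaults encode the field protocol used for
#' *Acropora hyacinthus* in Palau: ambient 30 degC; targets 34, 34.5 and
#' 35 degC; 3 h ramp; 3 h hold; 1 h cool-down; two daily cycles; two control
#' and three heated nubbins per colony (one per target temperature).
#'
#' @param base_temp ambient holding temperature, degC.
#' @param target_temps vector of target temperatures, degC; all must exceed
#'   `base_temp`.
#' @param ramp_hours,hold_hours,cool_hours durations of the three protocol
#'   phases, hours (all > 0).
#' @param n_days number of daily heat cycles.
#' @param n_control_nubbins,n_heated_nubbins replicates per colony.
#' @return an object of class `assay_design`.
#' @examples
#' d <- assay_design()
#' ramp_setpoint(d, 34.5, c(0, 1.5, 3, 6, 7, 12))
#' @export
assay_design <- function(base_temp = 30, target_temps = c(34, 34.5, 35),
                         ramp_hours = 3, hold_hours = 3, cool_hours = 1,
                         n_days = 2, n_control_nubbins = 2, n_heated_nubbins = 3) {
  check_number(base_temp, "base_temp", 0, 50)
  if (!is.numeric(target_temps) || length(target_temps) == 0L || any(!is.finite(target_temps)))
    stop_("'target_temps' must be a non-empty numeric vector")
  if (any(target_temps <= base_temp))
    stop_("all 'target_temps' must exceed 'base_temp'")
  check_number(ramp_hours, "ramp_hours", 0, strict = TRUE)
  check_number(hold_hours, "hold_hours", 0, strict = TRUE)
  check_number(cool_hours, "cool_hours", 0, strict = TRUE)
  structure(list(
    base_temp = base_temp, target_temps = target_temps,
    ramp_hours = ramp_hours, hold_hours = hold_hours, cool_hours = cool_hours,
    n_days = check_count(n_days, "n_days"),
    n_control_nubbins = check_count(n_control_nubbins, "n_control_nubbins"),
    n_heated_nubbins = check_count(n_heated_nubbins, "n_heated_nubbins")
  ), class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Heat-stress assay design\n")
  cat(sprintf("  base %g degC -> targets %s degC\n", x$base_temp,
              paste(x$target_temps, collapse = ", ")))
  cat(sprintf("  ramp %g h, hold %g h, cool %g h, %d day(s)\n",
              x$ramp_hours, x$hold_hours, x$cool_hours, x$n_days))
  cat(sprintf("  %d control + %d heated nubbins per colony\n",
              x$n_control_nubbins, x$n_heated_nubbins))
  invisible(x)
}

#' Tank setpoint temperature during the assay
#'
#' Piecewise-linear daily profile: linear ramp from base to target over
#' `ramp_hours`, constant hold, linear cool-down back to base, then base for
#' the rest of the day. The cycle repeats each day for `n_days`; after the
#' last day the setpoint stays at base.
#'
#' @param design an [assay_design()].
#' @param target_temp one of `design$target_temps`.
#' @param elapsed_hours time(s) since the start of the assay, hours (>= 0);
#'   vectorized.
#' @return numeric vector of setpoint temperatures, degC.
#' @export
ramp_setpoint <- function(design, target_temp, elapsed_hours) {
  stopifnot(inherits(design, "assay_design"))
  if (!isTRUE(any(abs(design$target_temps - target_temp) < 1e-9)))
    stop_(sprintf("unknown target_temp %g; valid targets: %s", target_temp,
                  paste(design$target_temps, collapse = ", ")))
  if (any(elapsed_hours < 0)) stop_("'elapsed_hours' must be >= 0")
  r <- design$ramp_hours; h <- design$hold_hours; cl <- design$cool_hours
  cycle_end <- r + h + cl
  day_in <- elapsed_hours %% 24
  day_no <- floor(elapsed_hours / 24)
  tt <- target_temp - design$base_temp
  up <- pmin(pmax(day_in / r, 0), 1)
  down <- pmin(pmax((day_in - r - h) / cl, 0), 1)
  frac <- ifelse(day_in >= cycle_end, 0, up - down)
  frac[day_no >= design$n_days] <- 0
  design$base_temp + tt * frac
}
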