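#' Annual linear extension and percent growth from repeat diameters
#'
#' Extension is annualized by 365.25/interval since field revisit intervals
#' are close to, but not exactly, one year; percent growth is relative to
#' the starting diameter and unit-free.
#'
#' @param diameter_start,diameter_end colony diameters (same units, > 0);
#'   vectorized.
#' @param interval_days days between measurements (> 0).
#' @param colony_id optional identifier(s).
#' @return data frame of class `growth_record`: `colony_id`,
#'   `diameter_start`, `diameter_end`, `interval_days`, `extension_cm_yr`,
#'   `percent_growth`, `excluded`, `reason`.
#' @examples
#' compute_growth(50, 54.8, 365.25)  # 4.8 cm/yr, 9.6%
#' @export
compute_growth <- function(diameter_start, diameter_end, interval_days,
                           colony_id = NULL) {
  if (any(!is.finite(diameter_start)) || any(diameter_start <= 0) ||
      any(!is.finite(diameter_end)) || any(diameter_end <= 0))
    stop_("diameters must be positive and finite")
  if (any(!is.finite(interval_days)) || any(interval_days <= 0))
    stop_("'interval_days' must be positive")
  n <- max(length(diameter_start), length(diameter_end), length(interval_days))
  if (is.null(colony_id)) colony_id <- paste0("C", seq_len(n))
  out <- data.frame(
    colony_id = colony_id,
    diameter_start = rep_len(diameter_start, n),
    diameter_end = rep_len(diameter_end, n),
    interval_days = rep_len(interval_days, n),
    stringsAsFactors = FALSE
  )
  out$extension_cm_yr <- (out$diameter_end - out$diameter_start) * 365.25 / out$interval_days
  out$percent_growth <- 100 * (out$diameter_end - out$diameter_start) / out$diameter_start
  out$excluded <- FALSE
  out$reason <- NA_character_
  class(out) <- c("growth_record", class(out))
  out
}

#' Exclude size decreases attributable to damage or disease
#'
#' Colonies whose percent change is strictly below the threshold (default
#' -10%, i.e. decreases *exceeding* 10%) are marked excluded; a decrease of
#' exactly 10% is retained. The filter is idempotent and keeps every record
#' (excluded rows are flagged, not dropped), so excluded + retained always
#' partition the input.
#'
#' @param records output of [compute_growth()].
#' @param threshold percent-change cutoff (default -10).
#' @return `records` with `excluded`/`reason` updated; the exclusion log
#'   (ids) is attached as attribute `exclusion_log`.
#' @export
filter_growth_outliers <- function(records, threshold = -10) {
  stopifnot(is.data.frame(records), "percent_growth" %in% names(records))
  check_number(threshold, "threshold")
  hit <- !is.na(records$percent_growth) & records$percent_growth < threshold
  records$excluded <- hit
  records$reason <- ifelse(hit, sprintf("decrease exceeding %g%%", -threshold), NA_character_)
  attr(records, "exclusion_log") <- records$colony_id[hit]
  records
}
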