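#' Symbiont retention score of a colony
#'
#' Retention is the mean heated-nubbin symbiont load, pooled across the
#' heat-treatment target temperatures, divided by the mean control-nubbin
#' load. Values above 1 are possible and deliberately not capped. Colonies
#' whose mean control load falls below `control_floor` are flagged and get
#' `NA` retention (the ratio is numerically unstable there).
#'
#' @param control_loads numeric vector of control-nubbin mean loads (or
#'   `replicate_summary` objects).
#' @param heated_loads numeric vector of heated-nubbin mean loads (one per
#'   target temperature), or `replicate_summary` objects.
#' @param control_floor minimum admissible mean control load.
#' @return list with `retention`, `control_mean`, `heated_mean`, `ok`.
#' @examples
#' retention_score(c(0.10, 0.12), c(0.08, 0.02, 0.05))  # 0.05 / 0.11
#' @export
retention_score <- function(control_loads, heated_loads, control_floor = 0.005) {
  as_loads <- function(v) {
    if (inherits(v, "replicate_summary")) v <- list(v)
    if (is.list(v) && all(vapply(v, inherits, TRUE, "replicate_summary")))
      v <- vapply(v, `[[`, 0, "mean_load")
    as.numeric(v)
  }
  ctl <- as_loads(control_loads); heat <- as_loads(heated_loads)
  if (length(ctl) == 0L || length(heat) == 0L)
    stop_("need at least one control and one heated load")
  cm <- mean(ctl); hm <- mean(heat)
  if (!is.finite(cm) || cm < control_floor) {
    return(list(retention = NA_real_, control_mean = cm, heated_mean = hm,
                ok = FALSE))
  }
  list(retention = hm / cm, control_mean = cm, heated_mean = hm, ok = TRUE)
}

#' Classify bleaching-resistant colonies by retention quantile
#'
#' A colony is resistant when its retention is at or above the empirical
#' quantile (default the 75th percentile, i.e. the top 25%). The quantile
#' uses linear interpolation between order statistics (R type 7); ties at
#' the threshold are included, so with heavy ties more than a quarter of
#' colonies can be labelled resistant (flagged degenerate when all are).
#'
#' @param colonies data frame with a `retention` column.
#' @param quantile probability cut (default 0.75).
#' @return `colonies` with a logical `resistant` column added; the threshold
#'   is attached as attribute `retention_threshold`, and `degenerate` flags
#'   an all-tied classification.
#' @export
classify_resistant <- function(colonies, quantile = 0.75) {
  stopifnot(is.data.frame(colonies), "retention" %in% names(colonies))
  check_number(quantile, "quantile", 0, 1)
  ret <- colonies$retention
  ok <- is.finite(ret)
  if (sum(ok) < 4) stop_("need at least 4 colonies with defined retention")
  thr <- unname(quantile(ret[ok], quantile, type = 7))
  colonies$resistant <- ifelse(ok, ret >= thr, NA)
  attr(colonies, "retention_threshold") <- thr
  attr(colonies, "degenerate") <- all(colonies$resistant[ok])
  colonies
}

quartile_members <- function(ret, which = c("top", "bottom")) {
  which <- match.arg(which)
  ok <- which(is.finite(ret))
  k <- max(1L, floor(length(ok) / 4))
  ord <- ok[order(ret[ok])]
  if (which == "top") utils::tail(ord, k) else utils::head(ord, k)
}

#' Contrast of top versus bottom retention quartiles
#'
#' Means of key phenotype and exposure variables for the colonies in the top
#' and bottom 25% of retention (group size `floor(n/4)`, ties broken by sort
#' order). Missing values are excluded per column with counts reported.
#'
#' @param colonies data frame with `retention` plus any of `control_load`,
#'   `heated_load`, `depth_m`, `above_31`, `above_32` columns.
#' @return object of class `quartile_contrast`: a data frame with rows
#'   `top25` and `bottom25` and one column per available variable, plus a
#'   matching `n` data frame of non-missing counts.
#' @export
summarize_quartile_contrast <- function(colonies) {
  stopifnot(is.data.frame(colonies), "retention" %in% names(colonies))
  if (nrow(colonies) < 4) stop_("need at least 4 colonies")
  vars <- intersect(c("control_load", "heated_load", "retention", "depth_m",
                      "above_31", "above_32"), names(colonies))
  top <- quartile_members(colonies$retention, "top")
  bot <- quartile_members(colonies$retention, "bottom")
  stat <- function(idx) vapply(vars, function(v) mean(colonies[[v]][idx], na.rm = TRUE), 0)
  cnt <- function(idx) vapply(vars, function(v) sum(is.finite(colonies[[v]][idx])), 0L)
  means <- rbind(top25 = stat(top), bottom25 = stat(bot))
  ns <- rbind(top25 = cnt(top), bottom25 = cnt(bot))
  structure(list(means = as.data.frame(means), n = as.data.frame(ns),
                 group_size = length(top)),
            class = "quartile_contrast")
}

#' @export
print.quartile_contrast <- function(x, ...) {
  cat(sprintf("Quartile contrast (groups of %d):\n", x$group_size))
  print(round(x$means, 4))
  invisible(x)
}

#' Fraction of resistant colonies per reef and per region
#'
#' @param colonies data frame with `reef_id`, logical `resistant`, and
#'   optionally `region`.
#' @return list with `reefs` (reef_id, n, n_resistant, fraction) and
#'   `regions` (pooled counts; NULL when no `region` column).
#' @export
reef_resistance_fraction <- function(colonies) {
  stopifnot(is.data.frame(colonies), all(c("reef_id", "resistant") %in% names(colonies)))
  ok <- !is.na(colonies$resistant)
  df <- colonies[ok, , drop = FALSE]
  tab <- function(key) {
    sp <- split(df$resistant, df[[key]])
    out <- data.frame(key = names(sp),
                      n = vapply(sp, length, 0L),
                      n_resistant = vapply(sp, sum, 0L),
                      stringsAsFactors = FALSE, row.names = NULL)
    out$fraction <- out$n_resistant / out$n
    names(out)[1] <- key
    out
  }
  list(reefs = tab("reef_id"),
       regions = if ("region" %in% names(df)) tab("region") else NULL)
}
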