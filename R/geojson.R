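#' Export reef summaries as a GeoJSON FeatureCollection
#'
#' One Point feature per reef with properties `reef_id`, `n`, `n_resistant`,
#' `fraction` and the mean exceedance counts. Reefs without coordinates are
#' skipped with a warning. The document follows RFC 7946 (WGS84 lon/lat
#' order).
#'
#' @param x a `pipeline_result`, or a data frame with `reef_id`, `lat`,
#'   `lon` and any property columns.
#' @param path optional file to write.
#' @return the GeoJSON structure (a list), invisibly when written to file.
#' @export
export_reef_geojson <- function(x, path = NULL) {
  if (inherits(x, "pipeline_result")) {
    coords <- stats::aggregate(cbind(lat, lon) ~ reef_id, data = x$colony_scores, FUN = mean)
    df <- merge(x$reef_fractions$reefs, coords, by = "reef_id")
    thr <- grep("^above_", names(x$reef_thermal), value = TRUE)
    df <- merge(df, x$reef_thermal[, c("reef_id", thr)], by = "reef_id", all.x = TRUE)
  } else {
    df <- x
  }
  stopifnot(is.data.frame(df), "reef_id" %in% names(df))
  has_coord <- all(c("lat", "lon") %in% names(df))
  features <- list()
  for (i in seq_len(nrow(df))) {
    if (!has_coord || !is.finite(df$lat[i]) || !is.finite(df$lon[i])) {
      warning(sprintf("reef %s skipped: missing coordinates", df$reef_id[i]), call. = FALSE)
      next
    }
    props <- as.list(df[i, setdiff(names(df), c("lat", "lon")), drop = FALSE])
    features[[length(features) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(df$lon[i], df$lat[i])),
      properties = props
    )
  }
  gj <- list(type = "FeatureCollection", features = features)
  if (!is.null(path)) {
    json <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 8, null = "null")
    # coordinates must stay an array even for the single-feature case
    writeLines(json, path)
    return(invisible(gj))
  }
  gj
}
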