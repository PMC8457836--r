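#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: either an in-memory
#' `reef_dataset` or a directory of input files, the gating configuration,
#' thermal thresholds, the resistance quantile, the growth exclusion
#' threshold, dip-test replicates, and one master seed that fans out to the
#' stochastic stages.
#'
#' @param dataset optional in-memory `reef_dataset`.
#' @param input_dir directory with colonies/samples/events/loggers CSVs
#'   (used when `dataset` is NULL).
#' @param gating a [gating_config()]; default matches the simulator.
#' @param thresholds thermal thresholds, degC.
#' @param quantile resistance quantile.
#' @param growth_threshold percent-change exclusion cutoff.
#' @param dip_B Monte-Carlo replicates for the dip test.
#' @param seed master seed.
#' @param output_dir optional directory for result files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = NULL, input_dir = NULL,
                            gating = default_gating_for_sim(),
                            thresholds = 31:35, quantile = 0.75,
                            growth_threshold = -10, dip_B = 1999,
                            seed = 1L, output_dir = NULL) {
  if (is.null(dataset) && is.null(input_dir))
    stop_("supply 'dataset' or 'input_dir'")
  structure(list(dataset = dataset, input_dir = input_dir, gating = gating,
                 thresholds = thresholds, quantile = quantile,
                 growth_threshold = growth_threshold,
                 dip_B = check_count(dip_B, "dip_B", 999),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

# Vectorized gating + replicate aggregation for the pipeline. Semantically
# identical to calling gate_and_estimate_load() per replicate table followed
# by aggregate_replicates() per sample (a pipeline test asserts equality);
# implemented with rowsum() so large event tables gate in milliseconds.
gate_stage <- function(events, samples, gating) {
  if (any(events$fsc < 0, na.rm = TRUE) || any(events$chl_fluor < 0, na.rm = TRUE))
    stop_("negative channel values")
  rep_v <- if ("replicate" %in% names(events)) events$replicate else 1L
  key <- paste(events$sample_id, rep_v, sep = "\r")
  symb <- events$chl_fluor > gating$chl_threshold
  coral <- !symb & events$fsc > gating$fsc_threshold
  ns <- rowsum(as.integer(symb), key)
  nc <- rowsum(as.integer(coral), key)
  ntot <- rowsum(rep(1L, nrow(events)), key)
  ncells <- ns + nc
  sid <- sub("\r.*$", "", rownames(ns))
  if (any(ncells < gating$min_cell_events)) {
    bad <- sid[which(ncells < gating$min_cell_events)[1]]
    stop_(sprintf("QC failure for sample '%s': fewer than %d cell events",
                  bad, gating$min_cell_events))
  }
  load <- if (gating$load_denominator == "cells") ns / ncells else ns / ntot
  mean_load <- tapply(load, sid, mean)
  cv <- tapply(load, sid, function(v) {
    if (length(v) < 2) NA_real_ else if (mean(v) > 0) sd(v) / mean(v) else NA_real_
  })
  nrep <- tapply(load, sid, length)
  out <- data.frame(
    sample_id = names(mean_load),
    mean_load = as.numeric(mean_load),
    cv = as.numeric(cv[names(mean_load)]),
    n_replicates = as.integer(nrep[names(mean_load)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$qc_pass <- is.na(out$cv) | out$cv <= gating$max_replicate_cv
  merge(samples, out, by = "sample_id", sort = FALSE)
}

score_stage <- function(sample_loads, colonies, quantile) {
  per_colony <- lapply(split(sample_loads, sample_loads$colony_id), function(df) {
    ctl <- df$mean_load[df$treatment == "control"]
    heat <- df$mean_load[df$treatment == "heated"]
    rs <- retention_score(ctl, heat)
    data.frame(colony_id = df$colony_id[1], control_load = rs$control_mean,
               heated_load = rs$heated_mean, retention = rs$retention,
               retention_ok = rs$ok, stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, per_colony)
  rownames(scores) <- NULL
  scores <- merge(colonies, scores, by = "colony_id", sort = FALSE)
  scores <- classify_resistant(scores, quantile)
  thr <- attr(scores, "retention_threshold")
  scores$retention_threshold <- thr  # survives later merges
  scores
}

#' Run the full phenotyping pipeline
#'
#' Stages, in order: gate cytometry events and aggregate replicate loads;
#' summarize logger series into per-reef exceedance counts; score colony
#' retention and classify resistant colonies; compute and filter growth;
#' run the statistical layer (bimodality of control loads, within/between
#' reef variance, reef effect ANOVA, the load-retention and load-growth
#' regressions, and the reef-level exposure vs. resistance tests). A failure
#' in any stage aborts with an error naming the stage; missing diameter
#' columns skip the growth stage with a warning.
#'
#' @param config a [pipeline_config()] (or a `reef_dataset`, which is
#'   wrapped with default settings).
#' @return list of class `pipeline_result`: `sample_loads`, `colony_scores`,
#'   `reef_thermal`, `reef_fractions`, `growth`, `stats`, `contrast`,
#'   `manifest`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(pop = population_params(n_colonies = 24, n_reefs = 6),
#'                        cyto = cytometry_sim_params(n_events = 400), seed = 2)
#' res <- run_pipeline(pipeline_config(dataset = ds, dip_B = 999))
#' res$stats$load_retention_ols$r_squared
#' }
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "reef_dataset")) config <- pipeline_config(dataset = config)
  stopifnot(inherits(config, "pipeline_config"))
  ds <- config$dataset %||% read_dataset(config$input_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  sample_loads <- stage("gate", gate_stage(ds$events, ds$samples, config$gating))
  reef_thermal <- stage("thermal", reef_thermal_table(ds$loggers, config$thresholds))
  scores <- stage("score", score_stage(sample_loads, ds$colonies, config$quantile))

  thr_cols <- paste0("above_", config$thresholds)
  scores <- merge(scores, reef_thermal[, c("reef_id", thr_cols)],
                  by = "reef_id", all.x = TRUE, sort = FALSE)

  growth <- NULL
  if (all(c("diameter_2018_cm", "diameter_2019_cm") %in% names(ds$colonies))) {
    growth <- stage("growth", {
      iv <- if ("interval_days" %in% names(ds$colonies)) ds$colonies$interval_days else 365.25
      g <- compute_growth(ds$colonies$diameter_2018_cm, ds$colonies$diameter_2019_cm,
                          iv, colony_id = ds$colonies$colony_id)
      filter_growth_outliers(g, config$growth_threshold)
    })
    scores <- merge(scores,
                    growth[, c("colony_id", "extension_cm_yr", "percent_growth", "excluded")],
                    by = "colony_id", all.x = TRUE, sort = FALSE)
  } else {
    warning("diameter columns missing; growth stage skipped", call. = FALSE)
  }

  fractions <- stage("score", reef_resistance_fraction(scores))
  contrast <- stage("score", summarize_quartile_contrast(scores))
  stats <- stage("stats", stats_stage(scores, reef_thermal, fractions, config))

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefheat")),
    seed = config$seed,
    config_hash = hash_obj(config[c("thresholds", "quantile", "growth_threshold",
                                    "dip_B", "seed")]),
    n_colonies = nrow(scores),
    n_samples = nrow(sample_loads),
    n_reefs = nrow(reef_thermal),
    n_growth_excluded = if (is.null(growth)) NA_integer_ else sum(growth$excluded),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )

  res <- structure(list(sample_loads = sample_loads, colony_scores = scores,
                        reef_thermal = reef_thermal, reef_fractions = fractions,
                        growth = growth, contrast = contrast, stats = stats,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_result(res, config$output_dir)
  res
}

stats_stage <- function(scores, reef_thermal, fractions, config) {
  loads <- scores$control_load
  out <- list()
  out$dip <- dip_test(loads[is.finite(loads)], B = config$dip_B,
                      seed = stage_seed(config$seed, "dip"))
  out$variance <- load_variance_decomposition(loads, scores$reef_id)
  out$reef_anova <- tryCatch(oneway_anova(loads, scores$reef_id),
                             error = function(e) NULL)
  out$load_retention_ols <- ols_fit(scores$retention, cbind(load = loads))
  if (!is.null(scores$percent_growth)) {
    keep <- !isTRUE_vec(scores$excluded)
    out$load_growth_ols <- ols_fit(scores$percent_growth[keep],
                                   cbind(load = loads[keep]))
    out$growth_full_ols <- tryCatch(
      ols_fit(scores$percent_growth[keep],
              cbind(load = loads[keep],
                    retention = scores$retention[keep],
                    size = scores$diameter_2018_cm[keep])),
      error = function(e) NULL)
  }
  # reef level: exposure vs fraction resistant
  reef <- merge(fractions$reefs, reef_thermal, by = "reef_id")
  if (nrow(reef) >= 3 && "above_32" %in% names(reef) &&
      var(reef$above_32) > 0 && var(reef$fraction) > 0) {
    out$reef_spearman_32 <- spearman_rank(reef$above_32, reef$fraction)
    out$reef_ols_32 <- ols_fit(reef$fraction, cbind(above_32 = reef$above_32))
    out$reef_ols_32_log1p <- ols_fit(reef$fraction, cbind(log1p_above_32 = log1p(reef$above_32)))
  }
  out
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Write pipeline outputs to a directory
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$sample_loads, file.path(dir, "sample_loads.csv"), row.names = FALSE)
  write.csv(result$colony_scores, file.path(dir, "colony_scores.csv"), row.names = FALSE)
  write.csv(result$reef_thermal, file.path(dir, "reef_thermal.csv"), row.names = FALSE)
  write.csv(result$reef_fractions$reefs, file.path(dir, "reef_fractions.csv"), row.names = FALSE)
  write.csv(cbind(group = rownames(result$contrast$means), result$contrast$means),
            file.path(dir, "quartile_contrast.csv"), row.names = FALSE)
  stats_flat <- lapply(result$stats, function(s) {
    if (inherits(s, "ols_result")) {
      list(r_squared = s$r_squared, p = s$p, n = s$n,
           coefficients = as.data.frame(s$coefficients))
    } else if (inherits(s, c("spearman_result", "dip_result", "anova_result"))) {
      unclass(s)
    } else s
  })
  jsonlite::write_json(c(stats_flat, list(manifest = result$manifest)),
                       file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)
  export_reef_geojson(result, file.path(dir, "reefs.geojson"))
  jsonlite::write_json(result$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
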