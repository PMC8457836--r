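#' Simulate a complete assay dataset with ground truth
#'
#' Builds the full input bundle the pipeline consumes: colony metadata with
#' repeat diameters, one sample per nubbin (two control nubbins at ambient
#' temperature plus one heated nubbin per target temperature), triplicate
#' cytometry event tables per sample, reef temperature-logger series with
#' injected warm spikes, and a `truth` list holding every generating
#' parameter and latent phenotype for recovery tests.
#'
#' Heated-nubbin true loads are `control_load * retention` clipped to
#' `[0, 1]`; per-reef spike counts vary around `spikes$n_spikes` (Poisson) so
#' reefs differ in thermal exposure. One master seed drives every stage
#' through deterministic per-stage sub-seeds.
#'
#' @param pop [population_params()].
#' @param cyto [cytometry_sim_params()]; `n_events` is the per-replicate
#'   event count.
#' @param spikes [spike_params()].
#' @param design [assay_design()]; sets nubbin counts and target
#'   temperatures.
#' @param n_replicates cytometry measurements per sample (triplicate by
#'   default).
#' @param loggers_per_reef logger moorings per reef.
#' @param seed master seed.
#' @return list of class `reef_dataset`: `colonies`, `samples`, `events`,
#'   `loggers`, `truth`.
#' @export
simulate_dataset <- function(pop = population_params(),
                             cyto = cytometry_sim_params(),
                             spikes = spike_params(),
                             design = assay_design(),
                             n_replicates = 3,
                             loggers_per_reef = 1,
                             seed = 1L) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  loggers_per_reef <- check_count(loggers_per_reef, "loggers_per_reef")
  pop$seed <- stage_seed(seed, "population")
  sim <- simulate_colony_population(pop)
  col <- sim$colonies

  targets <- design$target_temps
  if (design$n_heated_nubbins != length(targets))
    targets <- rep_len(targets, design$n_heated_nubbins)
  samples <- do.call(rbind, lapply(seq_len(nrow(col)), function(i) {
    ctl <- data.frame(colony_id = col$colony_id[i],
                      nubbin = paste0("ctl", seq_len(design$n_control_nubbins)),
                      treatment = "control", target_temp = NA_real_,
                      stringsAsFactors = FALSE)
    heat <- data.frame(colony_id = col$colony_id[i],
                       nubbin = paste0("heat", seq_along(targets)),
                       treatment = "heated", target_temp = targets,
                       stringsAsFactors = FALSE)
    rbind(ctl, heat)
  }))
  samples$sample_id <- paste(samples$colony_id, samples$nubbin, sep = "_")
  heated_true <- pmin(1, pmax(0, col$control_load * col$retention))
  samples$true_load <- ifelse(samples$treatment == "control",
                              col$control_load[match(samples$colony_id, col$colony_id)],
                              heated_true[match(samples$colony_id, col$colony_id)])

  # one vectorized draw for all samples x replicates x events; equivalent in
  # distribution to per-sample simulate_cytometry_sample calls (equivalence
  # is covered by a pipeline test) but orders of magnitude faster
  events <- with_seed(stage_seed(seed, "events"), {
    ne <- cyto$n_events
    n_tot <- nrow(samples) * n_replicates * ne
    sample_idx <- rep(seq_len(nrow(samples)), each = n_replicates * ne)
    replicate <- rep(rep(seq_len(n_replicates), each = ne), times = nrow(samples))
    tl <- samples$true_load[sample_idx]
    is_debris <- runif(n_tot) < cyto$debris_fraction
    is_symb <- !is_debris & (runif(n_tot) < tl)
    fsc_loc <- ifelse(is_debris, cyto$fsc_debris_location, cyto$fsc_cell_location)
    fsc_scl <- ifelse(is_debris, cyto$fsc_debris_scale, cyto$fsc_cell_scale)
    chl_loc <- ifelse(is_symb, cyto$symbiont_fluor_location, cyto$coral_fluor_location)
    chl_scl <- ifelse(is_symb, cyto$symbiont_fluor_scale, cyto$coral_fluor_scale)
    data.frame(sample_id = samples$sample_id[sample_idx],
               fsc = exp(fsc_loc + fsc_scl * rnorm(n_tot)),
               chl_fluor = exp(chl_loc + chl_scl * rnorm(n_tot)),
               replicate = replicate,
               stringsAsFactors = FALSE)
  })

  reef_ids <- unique(col$reef_id)
  spike_lambda <- spikes$n_spikes
  logger_truth <- list()
  log_list <- list()
  for (ri in seq_along(reef_ids)) {
    for (li in seq_len(loggers_per_reef)) {
      sp <- spikes
      sp$seed <- stage_seed(seed, paste0("logger_", reef_ids[ri], "_", li))
      sp$n_spikes <- with_seed(stage_seed(seed, paste0("nspk_", reef_ids[ri], "_", li)),
                               stats::rpois(1, spike_lambda))
      lid <- sprintf("%s_L%d", reef_ids[ri], li)
      ts <- simulate_temperature_series(sp, logger_id = lid, reef_id = reef_ids[ri])
      log_list[[lid]] <- ts$series
      logger_truth[[lid]] <- list(n_spikes = sp$n_spikes,
                                  spike_duration = sp$spike_duration,
                                  n_spike_samples = length(ts$spike_idx))
    }
  }
  loggers <- do.call(rbind, log_list)
  rownames(loggers) <- NULL

  colonies_meta <- col[, c("colony_id", "reef_id", "region", "reef_type",
                           "depth_m", "lat", "lon", "diameter_2018_cm",
                           "diameter_2019_cm", "interval_days")]
  structure(list(
    colonies = colonies_meta,
    samples = samples[, c("sample_id", "colony_id", "nubbin", "treatment", "target_temp")],
    events = events,
    loggers = loggers,
    truth = list(seed = seed, population = sim$truth,
                 phenotypes = col[, c("colony_id", "control_load", "retention",
                                      "heated_load", "growth_pct", "mixture_component")],
                 sample_true_loads = samples[, c("sample_id", "true_load")],
                 loggers = logger_truth)
  ), class = "reef_dataset")
}

#' Write a simulated dataset bundle as CSV/JSON files
#'
#' Writes `colonies.csv`, `samples.csv`, `events.csv`, `loggers.csv` and
#' `truth.json` into `dir`.
#'
#' @param dataset a `reef_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "reef_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(dataset$colonies, "colonies.csv")
  wr(dataset$samples, "samples.csv")
  wr(dataset$events, "events.csv")
  lg <- dataset$loggers
  lg$timestamp <- format(lg$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  wr(lg, "loggers.csv")
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = 12, dataframe = "columns")
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir directory containing the CSV files.
#' @return a `reef_dataset` (truth included when `truth.json` is present).
#' @export
read_dataset <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  loggers <- rd("loggers.csv")
  loggers$timestamp <- as.POSIXct(loggers$timestamp, tz = "UTC",
                                  format = "%Y-%m-%dT%H:%M:%SZ")
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(list(colonies = rd("colonies.csv"), samples = rd("samples.csv"),
                 events = rd("events.csv"), loggers = loggers, truth = truth),
            class = "reef_dataset")
}

#' Read temperature-logger records from CSV
#'
#' Expects columns `logger_id`, `reef_id`, `timestamp` (ISO-8601) and
#' `temp_c`; a `column_map` renames differently-labelled deposits, e.g.
#' `c(temp_c = "temperature")`.
#'
#' @param path CSV file.
#' @param column_map named character vector mapping standard names to the
#'   file's column names.
#' @return data frame of logger records.
#' @export
read_loggers <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% names(df))
        stop_("column '", column_map[[std]], "' not found in ", path)
      names(df)[names(df) == column_map[[std]]] <- std
    }
  }
  need <- c("logger_id", "reef_id", "timestamp", "temp_c")
  if (!all(need %in% names(df)))
    stop_("logger file needs columns: ", paste(need, collapse = ", "))
  if (is.character(df$timestamp)) {
    ts <- as.POSIXct(df$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
    if (anyNA(ts)) ts <- as.POSIXct(df$timestamp, tz = "UTC")
    df$timestamp <- ts
  }
  df
}
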