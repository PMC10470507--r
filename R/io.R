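# Plain-text exchange formats: long-format trace tables, batch-design
# configuration files (YAML or JSON) and CSV result writers.

#' Write / read long-format SRM trace tables
#'
#' The exchange format is CSV with columns `injection_id`, `compound`,
#' `fragment_index`, `time_min`, `intensity` — one row per acquired point.
#'
#' @param traces Trace tibble (e.g. `simulate_batch(...)$traces`).
#' @param path File path.
#' @return `write_traces` returns `path` invisibly; `read_traces` the tibble.
#' @export
write_traces <- function(traces, path) {
  need <- c("injection_id", "compound", "fragment_index", "time_min", "intensity")
  if (!all(need %in% names(traces))) {
    stop_invalid("Trace table misses required columns.")
  }
  utils::write.csv(traces[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("injection_id", "compound", "fragment_index", "time_min", "intensity")
  if (!all(need %in% names(df))) {
    stop_invalid("Trace file misses required columns.")
  }
  tibble::as_tibble(df[, need])
}

#' Read a batch design from a YAML or JSON config file
#'
#' The config mirrors the [batch_design()] / [sample_design()] arguments:
#' top-level acquisition fields plus a `samples` list; each sample entry gives
#' `sample_id`, `sample_type` and optionally `true_concentrations`, `spikes`
#' (maps compound -> pM), `sample_volume`, `extraction_efficiency`,
#' `resuspension_volume`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [batch_design()].
#' @export
read_batch_design <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  samples <- lapply(cfg$samples, function(s) {
    sample_design(
      sample_id = s$sample_id,
      sample_type = s$sample_type,
      true_concentrations = unlist(s$true_concentrations),
      sample_volume = s$sample_volume %||% 20,
      extraction_efficiency = unlist(s$extraction_efficiency) %||% 1,
      resuspension_volume = s$resuspension_volume %||% 100,
      spikes = unlist(s$spikes)
    )
  })
  levels <- cfg$calibration_levels_fmol
  if (is.null(levels)) {
    levels <- list(".default" = c(0, 25, 50, 250), "HET" = c(0, 5, 10, 50))
  } else {
    levels <- lapply(levels, as.numeric)
  }
  batch_design(
    samples = samples,
    calibration_levels_fmol = levels,
    injections_per_level = cfg$injections_per_level %||% 2,
    injection_volume = cfg$injection_volume %||% 5,
    noise_sd = cfg$noise_sd %||% 10,
    baseline_level = cfg$baseline_level %||% 50,
    response_rel_sd = cfg$response_rel_sd %||% 0,
    gain = cfg$gain %||% 1000,
    run_length = cfg$run_length %||% 12,
    dt_seconds = cfg$dt_seconds %||% 0.5,
    seed = cfg$seed %||% 1
  )
}

#' Write pipeline outputs as CSV
#'
#' @param quant An `srm_quantification` from [quantify_batch()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`areas.csv`, `curves.csv`,
#'   `results.csv`).
#' @export
write_quantification <- function(quant, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "areas.csv")
  utils::write.csv(quant$areas, p1, row.names = FALSE)
  curves <- dplyr::bind_rows(lapply(quant$curves, function(cv) {
    tibble::tibble(
      compound = cv$compound, matrix_group = cv$matrix_group,
      slope = cv$slope, intercept = cv$intercept, r_squared = cv$r_squared,
      residual_sd = cv$residual_sd, endogenous_fmol = cv$endogenous_fmol,
      valid = cv$valid, used_is_normalization = cv$used_is_normalization
    )
  }))
  p2 <- file.path(dir, "curves.csv")
  utils::write.csv(curves, p2, row.names = FALSE)
  p3 <- file.path(dir, "results.csv")
  utils::write.csv(quant$results, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
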