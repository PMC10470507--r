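# Synthetic SRM batch generator: Gaussian peaks per transition on a uniform
# time grid, additive baseline + Gaussian noise, optional per-injection
# response jitter, and a ground-truth ledger for parameter-recovery testing.

#' Describe one sample in a simulated batch
#'
#' @param sample_id Identifier.
#' @param sample_type One of `"environmental_dissolved"`, `"spent_medium"`,
#'   `"medium_blank"`, `"particulate"`, `"qc_pool"`, `"calibration"`.
#'   QC pools are constructed with [make_qc_pool()], not specified directly.
#' @param true_concentrations Named numeric, pM per compound in the original
#'   sample (for `qc_pool` samples: pM in the resuspended vial).
#' @param sample_volume Sample volume in mL.
#' @param extraction_efficiency Scalar or named per-compound fraction in (0, 1]
#'   modelling SPE loss.
#' @param resuspension_volume Vial resuspension volume in µL (study values:
#'   100, 200 or 400).
#' @param spikes Named numeric, pM added to the sample before extraction
#'   (recovery spikes, heavy internal standard).
#' @return A `sample_design` object.
#' @export
sample_design <- function(sample_id,
                          sample_type = c("environmental_dissolved", "spent_medium",
                                          "medium_blank", "particulate", "qc_pool",
                                          "calibration"),
                          true_concentrations = c(),
                          sample_volume = 20,
                          extraction_efficiency = 1,
                          resuspension_volume = 100,
                          spikes = c()) {
  sample_type <- match.arg(sample_type)
  check_positive_scalar(sample_volume, "sample_volume")
  check_positive_scalar(resuspension_volume, "resuspension_volume")
  if (any(extraction_efficiency <= 0) || any(extraction_efficiency > 1)) {
    stop_invalid("`extraction_efficiency` must lie in (0, 1].")
  }
  if (length(true_concentrations) && is.null(names(true_concentrations))) {
    stop_invalid("`true_concentrations` must be named by compound.")
  }
  if (length(spikes) && is.null(names(spikes))) {
    stop_invalid("`spikes` must be named by compound.")
  }
  structure(
    list(
      sample_id = sample_id,
      sample_type = sample_type,
      true_concentrations = true_concentrations,
      sample_volume = sample_volume,
      extraction_efficiency = extraction_efficiency,
      resuspension_volume = resuspension_volume,
      spikes = spikes
    ),
    class = "sample_design"
  )
}

#' Describe a simulated SRM batch
#'
#' Bundles the samples to inject with the acquisition and noise parameters.
#' Defaults mirror the study design: standard additions of 0/25/50/250 fmol
#' (0/5/10/50 fmol for HET), duplicate 5 µL injections, a 12-min run sampled
#' every 0.5 s.
#'
#' @param samples List of [sample_design()] objects.
#' @param calibration_levels_fmol Named list of added-amount series per
#'   compound; the entry `".default"` applies to compounds not listed. All
#'   series must share a length, be non-negative and include 0.
#' @param injections_per_level Replicate injections per calibration level and
#'   per sample (default 2, the study's duplicate injections).
#' @param injection_volume Injection volume, µL (default 5).
#' @param noise_sd Additive Gaussian noise SD per time point, intensity units.
#' @param baseline_level Constant baseline, intensity units.
#' @param response_rel_sd Log-scale SD of a per-injection multiplicative
#'   response factor (common-mode across all transitions of one injection);
#'   0 disables it.
#' @param gain Instrument response gain, intensity units per fmol at unit
#'   relative intensity (arbitrary: the instrument's true gain is unknown).
#' @param run_length Chromatographic run length, minutes.
#' @param dt_seconds Sampling interval, seconds.
#' @param seed Integer seed; all stochastic draws for a batch flow from it.
#' @return A `batch_design` object.
#' @export
batch_design <- function(samples = list(),
                         calibration_levels_fmol = list(
                           ".default" = c(0, 25, 50, 250),
                           "HET" = c(0, 5, 10, 50)
                         ),
                         injections_per_level = 2,
                         injection_volume = 5,
                         noise_sd = 10,
                         baseline_level = 50,
                         response_rel_sd = 0,
                         gain = 1000,
                         run_length = 12,
                         dt_seconds = 0.5,
                         seed = 1) {
  if (injections_per_level < 1) {
    stop_invalid("`injections_per_level` must be at least 1.")
  }
  check_positive_scalar(injection_volume, "injection_volume")
  check_positive_scalar(gain, "gain")
  check_positive_scalar(run_length, "run_length")
  check_positive_scalar(dt_seconds, "dt_seconds")
  if (noise_sd < 0 || baseline_level < 0 || response_rel_sd < 0) {
    stop_invalid("`noise_sd`, `baseline_level` and `response_rel_sd` must be non-negative.")
  }
  lens <- integer(0)
  for (nm in names(calibration_levels_fmol)) {
    lv <- calibration_levels_fmol[[nm]]
    if (any(lv < 0)) stop_invalid("Calibration levels must be non-negative.")
    if (!any(lv == 0)) stop_invalid("Calibration levels must include 0.")
    lens <- c(lens, length(lv))
  }
  if (length(unique(lens)) > 1) {
    stop_invalid("All calibration level series must have the same length.")
  }
  structure(
    list(
      samples = samples,
      calibration_levels_fmol = calibration_levels_fmol,
      injections_per_level = as.integer(injections_per_level),
      injection_volume = injection_volume,
      noise_sd = noise_sd,
      baseline_level = baseline_level,
      response_rel_sd = response_rel_sd,
      gain = gain,
      run_length = run_length,
      dt_seconds = dt_seconds,
      seed = as.integer(seed)
    ),
    class = "batch_design"
  )
}

calibration_levels_for <- function(design, compound_name) {
  lv <- design$calibration_levels_fmol[[compound_name]]
  if (is.null(lv)) lv <- design$calibration_levels_fmol[[".default"]]
  lv
}

#' Uniform acquisition time grid for a batch design
#' @param design A [batch_design()].
#' @return Numeric vector of times in minutes.
#' @export
time_grid <- function(design) {
  seq(0, design$run_length, by = design$dt_seconds / 60)
}

#' On-column amount after extraction and injection
#'
#' Carries a dissolved-phase concentration through the SPE/resuspension/
#' injection volume chain:
#' `fmol = conc_pM * sample_volume_mL * efficiency * injection_uL / resuspension_uL`
#' (pM × mL gives fmol directly).
#'
#' @param concentration Concentration in the sample, pM.
#' @param sample_volume Extracted sample volume, mL.
#' @param efficiency Extraction efficiency in (0, 1].
#' @param resuspension_volume Vial volume, µL.
#' @param injection_volume Injected volume, µL.
#' @return Amount on column, fmol.
#' @export
#' @examples
#' simulate_extraction(100, 20, 0.5, 100, 5)  # 50 fmol
simulate_extraction <- function(concentration, sample_volume, efficiency,
                                resuspension_volume, injection_volume) {
  if (any(concentration < 0)) stop_invalid("`concentration` must be non-negative.")
  check_positive_scalar(sample_volume, "sample_volume")
  check_positive_scalar(resuspension_volume, "resuspension_volume")
  check_positive_scalar(injection_volume, "injection_volume")
  if (!is.numeric(efficiency) || any(efficiency <= 0) || any(efficiency > 1)) {
    stop_invalid("`efficiency` must lie in (0, 1].")
  }
  concentration * sample_volume * efficiency * injection_volume / resuspension_volume
}

# Safe named lookup defaulting to 0.
lookup0 <- function(x, nm) {
  if (length(x) && nm %in% names(x) && is.finite(x[[nm]])) x[[nm]] else 0
}

# pM-equivalent concentration in the resuspended vial for one compound.
vial_concentration <- function(sample, compound_name) {
  conc <- lookup0(sample$true_concentrations, compound_name)
  spike <- lookup0(sample$spikes, compound_name)
  if (sample$sample_type == "qc_pool") {
    # pools are specified directly at the vial level; spikes not applicable
    return(conc)
  }
  eff <- sample$extraction_efficiency
  if (!is.null(names(eff))) {
    eff <- if (compound_name %in% names(eff)) eff[[compound_name]] else 1
  }
  (conc + spike) * eff * sample$sample_volume * 1000 / sample$resuspension_volume
}

# fmol reaching the column from one vial injection.
vial_on_column_fmol <- function(vial_conc_pM, injection_volume_uL) {
  vial_conc_pM * injection_volume_uL / 1000
}

#' Pool equal portions of samples into a QC pool
#'
#' Emulates the study's quality-control pools: equal portions of every sample
#' of one matrix grouping are combined, so the pool's vial-level concentration
#' per compound is the arithmetic mean of the members' post-extraction vial
#' concentrations.
#'
#' @param samples List of [sample_design()] objects, all of one sample type.
#' @param pool_id Identifier for the pool (default `"QC_pool"`).
#' @param compounds Optional character vector of compound names to pool; by
#'   default the union of names seen in the members' concentrations and spikes.
#' @return A `sample_design` with `sample_type = "qc_pool"` whose
#'   `true_concentrations` are vial-level pM.
#' @export
make_qc_pool <- function(samples, pool_id = "QC_pool", compounds = NULL) {
  if (length(samples) < 1) stop_invalid("Need at least one sample to pool.")
  types <- vapply(samples, `[[`, character(1), "sample_type")
  if (length(unique(types)) > 1) {
    stop_invalid("QC pools must combine samples of a single matrix grouping.")
  }
  if (is.null(compounds)) {
    compounds <- unique(unlist(lapply(samples, function(s) {
      c(names(s$true_concentrations), names(s$spikes))
    })))
  }
  vial <- vapply(compounds, function(cmp) {
    mean(vapply(samples, vial_concentration, numeric(1), compound_name = cmp))
  }, numeric(1))
  pool <- sample_design(
    sample_id = pool_id,
    sample_type = "qc_pool",
    true_concentrations = vial,
    sample_volume = samples[[1]]$sample_volume,
    resuspension_volume = samples[[1]]$resuspension_volume
  )
  attr(pool, "matrix_group") <- unique(types)
  pool
}

# Noise-free Gaussian transition signal on a grid.
transition_signal <- function(time_min, fmol, rel_intensity, rt, sigma, gain) {
  gain * fmol * rel_intensity * exp(-(time_min - rt)^2 / (2 * sigma^2))
}

#' Simulate SRM traces for one compound in one injection
#'
#' For each fragment transition the signal is a Gaussian centred at the
#' compound's retention time,
#' `gain * fmol * rel_intensity * exp(-(t - RT)^2 / (2 sigma^2))`,
#' plus a constant baseline and i.i.d. Gaussian noise. Identical
#' `(compound, fmol, seed)` yield identical traces.
#'
#' @param compound A [compound_spec()].
#' @param on_column_fmol Amount on column, fmol (>= 0).
#' @param design A [batch_design()] supplying grid, gain, baseline and noise.
#' @param seed Integer seed for the noise draws.
#' @param response_factor Multiplicative response factor for this injection
#'   (default 1; used by [simulate_batch()] for common-mode area jitter).
#' @return Tibble with columns `fragment_index`, `time_min`, `intensity`.
#' @export
simulate_traces <- function(compound, on_column_fmol, design, seed = design$seed,
                            response_factor = 1) {
  if (!is_scalar_number(on_column_fmol) || on_column_fmol < 0) {
    stop_invalid("`on_column_fmol` must be a non-negative number.")
  }
  grid <- time_grid(design)
  n_frag <- length(compound$fragment_mzs)
  with_local_seed(seed, {
    traces <- lapply(seq_len(n_frag), function(k) {
      sig <- response_factor * transition_signal(
        grid, on_column_fmol, compound$fragment_rel_intensities[k],
        compound$retention_time, compound$peak_sigma, design$gain
      )
      noise <- if (design$noise_sd > 0) stats::rnorm(length(grid), 0, design$noise_sd) else 0
      tibble::tibble(
        fragment_index = k,
        time_min = grid,
        intensity = sig + design$baseline_level + noise
      )
    })
    dplyr::bind_rows(traces)
  })
}

#' Simulate a full SRM batch with ground truth
#'
#' Generates every injection of a batch: plain (duplicate) injections for each
#' sample and, for each QC pool, a standard-addition calibration series at the
#' design's per-compound levels. Returns the long-format traces together with
#' a ground-truth ledger recording the true on-column amount behind every
#' (injection, compound) pair. Fully reproducible from `design$seed`.
#'
#' @param design A [batch_design()].
#' @param panel Named list of [compound_spec()]s (default [make_default_panel()]).
#' @return An object of class `srm_batch`: a list with `traces` (tibble:
#'   `injection_id`, `compound`, `fragment_index`, `time_min`, `intensity`),
#'   `truth` (tibble: `injection_id`, `sample_id`, `sample_type`,
#'   `level_index`, `compound`, `added_fmol`, `true_fmol`, `response_factor`),
#'   `design` and `panel`.
#' @export
simulate_batch <- function(design, panel = make_default_panel()) {
  # Injection plan: one row per physical injection.
  plan <- list()
  for (s in design$samples) {
    if (s$sample_type == "qc_pool") {
      n_lev <- length(design$calibration_levels_fmol[[1]])
      for (lev in seq_len(n_lev)) {
        for (r in seq_len(design$injections_per_level)) {
          plan[[length(plan) + 1]] <- list(
            injection_id = sprintf("%s_L%d_inj%d", s$sample_id, lev, r),
            sample = s, level_index = lev
          )
        }
      }
    } else {
      for (r in seq_len(design$injections_per_level)) {
        plan[[length(plan) + 1]] <- list(
          injection_id = sprintf("%s_inj%d", s$sample_id, r),
          sample = s, level_index = NA_integer_
        )
      }
    }
  }

  grid <- time_grid(design)
  with_local_seed(design$seed, {
    truth_rows <- vector("list", length(plan))
    trace_rows <- vector("list", length(plan))
    for (i in seq_along(plan)) {
      inj <- plan[[i]]
      s <- inj$sample
      rf <- if (design$response_rel_sd > 0) {
        exp(stats::rnorm(1, 0, design$response_rel_sd))
      } else 1
      cmp_truth <- vector("list", length(panel))
      cmp_traces <- vector("list", length(panel))
      for (j in seq_along(panel)) {
        cmp <- panel[[j]]
        vial <- vial_concentration(s, cmp$name)
        endo_fmol <- vial_on_column_fmol(vial, design$injection_volume)
        # authentic-standard additions apply to analytes only; the heavy
        # internal standard is never part of the addition mix
        added <- if (!is.na(inj$level_index) && cmp$role == "analyte") {
          calibration_levels_for(design, cmp$name)[inj$level_index]
        } else NA_real_
        fmol <- endo_fmol + ifelse(is.na(added), 0, added)
        cmp_truth[[j]] <- tibble::tibble(
          injection_id = inj$injection_id,
          sample_id = s$sample_id,
          sample_type = s$sample_type,
          level_index = inj$level_index,
          compound = cmp$name,
          added_fmol = added,
          true_fmol = fmol,
          response_factor = rf
        )
        n_frag <- length(cmp$fragment_mzs)
        sig <- lapply(seq_len(n_frag), function(k) {
          base_sig <- rf * transition_signal(
            grid, fmol, cmp$fragment_rel_intensities[k],
            cmp$retention_time, cmp$peak_sigma, design$gain
          )
          noise <- if (design$noise_sd > 0) stats::rnorm(length(grid), 0, design$noise_sd) else 0
          tibble::tibble(
            injection_id = inj$injection_id,
            compound = cmp$name,
            fragment_index = k,
            time_min = grid,
            intensity = base_sig + design$baseline_level + noise
          )
        })
        cmp_traces[[j]] <- dplyr::bind_rows(sig)
      }
      truth_rows[[i]] <- dplyr::bind_rows(cmp_truth)
      trace_rows[[i]] <- dplyr::bind_rows(cmp_traces)
    }
    structure(
      list(
        traces = dplyr::bind_rows(trace_rows),
        truth = dplyr::bind_rows(truth_rows),
        design = design,
        panel = panel
      ),
      class = "srm_batch"
    )
  })
}

#' @export
print.srm_batch <- function(x, ...) {
  cat(sprintf("<srm_batch> %d injections, %d compounds, %d trace points\n",
              length(unique(x$truth$injection_id)),
              length(unique(x$truth$compound)),
              nrow(x$traces)))
  invisible(x)
}
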