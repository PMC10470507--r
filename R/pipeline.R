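# End-to-end batch quantification: integrate -> select quantifiers ->
# (optionally) IS-normalize -> standard-addition calibration -> LOD/LOQ ->
# recovery-corrected per-sample concentrations with detection status.

# Rescale fmol-scale thresholds onto a sample's (optionally recovery-
# corrected) concentration scale.
scale_thresholds <- function(th, chain, recovery_pct = 100) {
  th$lod <- apply_recovery(on_column_to_sample_conc(th$lod_fmol, chain), recovery_pct)
  th$loq <- apply_recovery(on_column_to_sample_conc(th$loq_fmol, chain), recovery_pct)
  th
}

sample_chain <- function(s, design) {
  volume_chain(s$sample_volume, s$resuspension_volume, design$injection_volume)
}

# Summed quantifier response per (injection, compound).
summed_responses <- function(areas, selection) {
  quant <- selection[selection$quantifier, c("compound", "fragment_index")]
  keep <- dplyr::inner_join(areas, quant, by = c("compound", "fragment_index"))
  dplyr::summarise(
    dplyr::group_by(keep, .data$injection_id, .data$compound),
    response = sum(.data$area), .groups = "drop"
  )
}

#' Quantify every sample in a simulated or imported batch
#'
#' Runs the full post-acquisition pipeline on an `srm_batch`: integrates all
#' traces in a retention-time window per compound, selects quantifier
#' transitions against the blanks, decides heavy-internal-standard
#' normalization from replicate QC-pool injections (when at least 3 are
#' available), fits a standard-addition curve per analyte from the QC-pool
#' spike series, derives blank-based LOD/LOQ, converts and recovery-corrects
#' every sample's replicate injections, evaluates the four sub-LOQ criteria
#' where concentrations land between LOD and LOQ, and classifies each result.
#'
#' @param batch An [simulate_batch()] result, or an equivalent list with
#'   `traces`, `truth`, `design`, `panel`.
#' @param recoveries Named list (by compound) of [percent_recovery()] /
#'   [assumed_recovery()] estimates or bare percent values; compounds not
#'   listed use 100%.
#' @param half_width Integration window half-width, minutes.
#' @param use_is_normalization Consider IS normalization (default TRUE; it is
#'   only applied where the QC-replicate RSD rule favours it).
#' @param classify_on Scale for nd/nq classification: `"corrected"` (default)
#'   or `"uncorrected"`.
#' @return An `srm_quantification` list: `areas`, `selection`, `responses`,
#'   `normalization`, `curves`, `blank_fmol`, `thresholds`, `results`
#'   (tibble of [quantify_sample()] rows).
#' @export
quantify_batch <- function(batch, recoveries = list(), half_width = 0.2,
                           use_is_normalization = TRUE,
                           classify_on = c("corrected", "uncorrected")) {
  classify_on <- match.arg(classify_on)
  design <- batch$design
  panel <- batch$panel
  analytes <- names(panel)[vapply(panel, function(p) p$role == "analyte", logical(1))]
  is_name <- names(panel)[vapply(panel, function(p) p$role == "heavy_internal_standard",
                                 logical(1))]
  meta <- dplyr::distinct(batch$truth, .data$injection_id, .data$sample_id,
                          .data$sample_type, .data$level_index)

  areas <- integrate_batch(batch$traces, panel, half_width)
  areas <- dplyr::left_join(
    areas,
    batch$truth[, c("injection_id", "compound", "added_fmol")],
    by = c("injection_id", "compound")
  )
  areas <- dplyr::left_join(areas, meta, by = "injection_id")

  cal_areas <- areas[areas$sample_type == "qc_pool", ]
  blank_areas <- areas[areas$sample_type == "medium_blank", ]
  if (nrow(cal_areas) == 0) {
    stop_invalid("Batch contains no QC-pool calibration injections.")
  }
  selection <- select_quantifier_transitions(
    cal_areas, if (nrow(blank_areas)) blank_areas else NULL
  )
  responses <- summed_responses(areas, selection)
  responses <- dplyr::left_join(responses, meta, by = "injection_id")
  responses <- dplyr::left_join(
    responses,
    dplyr::distinct(batch$truth[, c("injection_id", "compound", "added_fmol")]),
    by = c("injection_id", "compound")
  )

  # --- IS normalization decision from unspiked QC-pool replicates -----------
  normalization <- list()
  norm_flags <- stats::setNames(rep(FALSE, length(analytes)), analytes)
  if (use_is_normalization && length(is_name) == 1) {
    qc_resp <- responses[responses$sample_type == "qc_pool", ]
    zero_inj <- unique(qc_resp$injection_id[!is.na(qc_resp$added_fmol) &
                                              qc_resp$added_fmol == 0])
    qc0 <- qc_resp[qc_resp$injection_id %in% zero_inj, ]
    is_resp <- qc0[qc0$compound == is_name, c("injection_id", "response")]
    if (nrow(is_resp) >= 3 && all(is_resp$response > 0)) {
      for (cmp in analytes) {
        a <- qc0[qc0$compound == cmp, ]
        a <- dplyr::inner_join(a, is_resp, by = "injection_id",
                               suffix = c("", "_is"))
        if (nrow(a) >= 3) {
          dec <- decide_is_normalization(a$response, a$response_is, compound = cmp)
          normalization[[cmp]] <- dec
          norm_flags[[cmp]] <- isTRUE(dec$normalize)
        }
      }
    }
  }

  # attach per-injection IS response for normalized compounds
  is_by_inj <- NULL
  if (any(norm_flags) && length(is_name) == 1) {
    is_by_inj <- responses[responses$compound == is_name,
                           c("injection_id", "response")]
    names(is_by_inj)[2] <- "is_response"
  }
  effective_response <- function(df, cmp) {
    if (!isTRUE(norm_flags[[cmp]])) return(df$response)
    x <- dplyr::left_join(df, is_by_inj, by = "injection_id")
    df$response / x$is_response
  }

  # --- standard-addition curves per analyte ---------------------------------
  matrix_group <- unique(meta$sample_id[meta$sample_type == "qc_pool"])[1]
  curves <- list()
  for (cmp in analytes) {
    ca <- responses[responses$sample_type == "qc_pool" & responses$compound == cmp, ]
    curve <- fit_standard_addition(ca$added_fmol, effective_response(ca, cmp),
                                   compound = cmp, matrix_group = matrix_group)
    curve$used_is_normalization <- isTRUE(norm_flags[[cmp]])
    curves[[cmp]] <- curve
  }

  # --- blank amounts and fmol-scale thresholds ------------------------------
  blank_fmol <- list()
  thresholds_fmol <- list()
  blank_resp <- responses[responses$sample_type == "medium_blank", ]
  for (cmp in analytes) {
    if (!curves[[cmp]]$valid) next
    br <- blank_resp[blank_resp$compound == cmp, ]
    if (nrow(br) >= 3) {
      amt <- response_to_amount(effective_response(br, cmp), curves[[cmp]])$fmol
      blank_fmol[[cmp]] <- amt
      thresholds_fmol[[cmp]] <- compute_lod_loq(amt, chain = NULL, compound = cmp,
                                                matrix_group = matrix_group)
    }
  }

  # mean summed blank area (all fragments) per compound, for sub-LOQ (iv)
  blank_area_mean <- stats::setNames(rep(NA_real_, length(analytes)), analytes)
  if (nrow(blank_areas)) {
    for (cmp in analytes) {
      ba <- blank_areas[blank_areas$compound == cmp, ]
      if (nrow(ba)) {
        per_inj <- tapply(ba$area, ba$injection_id, sum)
        blank_area_mean[[cmp]] <- mean(per_inj)
      }
    }
  }

  # authentic-standard fragment pattern: highest calibration level, per
  # fragment mean over its replicate injections
  standard_pattern <- function(cmp) {
    ca <- cal_areas[cal_areas$compound == cmp & !is.na(cal_areas$added_fmol), ]
    if (!nrow(ca)) return(NULL)
    top <- ca[ca$added_fmol == max(ca$added_fmol), ]
    out <- dplyr::summarise(
      dplyr::group_by(top, .data$fragment_index),
      area = mean(.data$area), apex_time = mean(.data$apex_time),
      .groups = "drop"
    )
    out
  }

  # --- per-sample quantification --------------------------------------------
  recovery_for <- function(cmp) {
    r <- recoveries[[cmp]]
    if (is.null(r)) 100 else r
  }
  sample_list <- Filter(function(s) s$sample_type != "qc_pool", design$samples)
  results <- list()
  thresholds_out <- list()
  for (s in sample_list) {
    chain <- sample_chain(s, design)
    for (cmp in analytes) {
      if (!curves[[cmp]]$valid) next
      rr <- responses[responses$sample_id == s$sample_id &
                        responses$compound == cmp, ]
      if (!nrow(rr)) next
      rec <- recovery_for(cmp)
      rec_pct <- if (inherits(rec, "recovery_estimate")) rec$percent_recovery else rec
      th <- NULL
      if (!is.null(thresholds_fmol[[cmp]])) {
        th <- scale_thresholds(
          thresholds_fmol[[cmp]], chain,
          if (classify_on == "corrected") rec_pct else 100
        )
        thresholds_out[[paste(s$sample_id, cmp, sep = ".")]] <- th
      }
      # provisional classification to see whether sub-LOQ evaluation applies
      resp_eff <- effective_response(rr, cmp)
      subloq <- NULL
      if (!is.null(th)) {
        fmol_hat <- mean(response_to_amount(resp_eff, curves[[cmp]])$fmol)
        conc_hat <- on_column_to_sample_conc(fmol_hat, chain)
        if (classify_on == "corrected") conc_hat <- apply_recovery(conc_hat, rec_pct)
        if (conc_hat < th$loq && conc_hat >= th$lod) {
          std <- standard_pattern(cmp)
          cand <- areas[areas$sample_id == s$sample_id & areas$compound == cmp, ]
          cand <- dplyr::summarise(
            dplyr::group_by(cand, .data$fragment_index),
            area = mean(.data$area), apex_time = mean(.data$apex_time),
            .groups = "drop"
          )
          bl <- blank_area_mean[[cmp]]
          if (!is.null(std) && nrow(std) >= 2 && is.finite(bl)) {
            subloq <- evaluate_subloq(cand, std, bl)
          }
        }
      }
      results[[length(results) + 1]] <- quantify_sample(
        resp_eff, curves[[cmp]], chain, recovery = rec,
        thresholds = th, subloq = subloq, sample_id = s$sample_id,
        classify_on = classify_on
      )
    }
  }

  structure(
    list(
      areas = areas,
      selection = selection,
      responses = responses,
      normalization = normalization,
      curves = curves,
      blank_fmol = blank_fmol,
      thresholds = thresholds_out,
      results = dplyr::bind_rows(results)
    ),
    class = "srm_quantification"
  )
}

#' @export
print.srm_quantification <- function(x, ...) {
  cat(sprintf("<srm_quantification> %d results, %d curves\n",
              nrow(x$results), length(x$curves)))
  invisible(x)
}

#' Measure percent recovery from a spiked/unspiked sample pair
#'
#' Convenience wrapper: pulls both samples' uncorrected concentrations for one
#' compound out of a [quantify_batch()] result and applies the
#' spike-difference formula.
#'
#' @param quant An `srm_quantification`.
#' @param compound Compound name.
#' @param spiked_id,unspiked_id Sample ids of the pair.
#' @param spike_pM Added concentration, pM.
#' @return A [percent_recovery()] estimate.
#' @export
recovery_from_pair <- function(quant, compound, spiked_id, unspiked_id, spike_pM) {
  res <- quant$results
  pick <- function(sid) {
    r <- res[res$sample_id == sid & res$compound == compound, ]
    if (nrow(r) != 1) stop_invalid(sprintf("No unique result for %s / %s.", sid, compound))
    r$conc_uncorrected
  }
  percent_recovery(pick(spiked_id), pick(unspiked_id), spike_pM,
                   compound = compound)
}
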