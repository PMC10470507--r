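# On-column amounts -> in-sample concentrations, recovery correction, and
# per-sample result assembly.

#' Volume chain linking sample to column
#'
#' @param sample_volume Extracted sample volume, mL.
#' @param resuspension_volume Vial volume, µL.
#' @param injection_volume Injected volume, µL (<= resuspension volume).
#' @param dilution_factor Post-resuspension dilution (default 1).
#' @return A `volume_chain` object.
#' @export
volume_chain <- function(sample_volume, resuspension_volume, injection_volume,
                         dilution_factor = 1) {
  check_positive_scalar(sample_volume, "sample_volume")
  check_positive_scalar(resuspension_volume, "resuspension_volume")
  check_positive_scalar(injection_volume, "injection_volume")
  check_positive_scalar(dilution_factor, "dilution_factor")
  if (injection_volume > resuspension_volume) {
    stop_invalid("`injection_volume` cannot exceed `resuspension_volume`.")
  }
  structure(
    list(sample_volume = sample_volume,
         resuspension_volume = resuspension_volume,
         injection_volume = injection_volume,
         dilution_factor = dilution_factor),
    class = "volume_chain"
  )
}

#' Convert an on-column amount to an in-sample concentration
#'
#' `conc_pM = fmol * (resuspension / injection) * dilution / sample_volume_mL`
#' (fmol per mL is numerically pM). This inverts the extraction chain apart
#' from the extraction efficiency, which is handled by recovery correction.
#'
#' @param fmol On-column amount(s), fmol (>= 0).
#' @param chain A [volume_chain()].
#' @return Concentration(s) in pM.
#' @export
#' @examples
#' on_column_to_sample_conc(50, volume_chain(20, 100, 5))  # 50 pM
on_column_to_sample_conc <- function(fmol, chain) {
  if (!inherits(chain, "volume_chain")) stop_invalid("`chain` must be a volume_chain.")
  if (any(fmol < 0)) stop_invalid("`fmol` must be non-negative.")
  fmol * (chain$resuspension_volume / chain$injection_volume) *
    chain$dilution_factor / chain$sample_volume
}

#' Correct a concentration for percent recovery
#'
#' @param conc Concentration(s).
#' @param recovery_percent Percent recovery in (0, 200].
#' @return `conc * 100 / recovery_percent`.
#' @export
#' @examples
#' apply_recovery(25, 50)  # 50
apply_recovery <- function(conc, recovery_percent) {
  if (!is_scalar_number(recovery_percent) ||
      recovery_percent <= 0 || recovery_percent > 200) {
    stop_invalid("`recovery_percent` must lie in (0, 200].")
  }
  conc * 100 / recovery_percent
}

#' Quantify one compound in one sample
#'
#' Converts replicate-injection responses to on-column amounts with the
#' matrix-matched calibration curve, averages replicates on the amount scale,
#' converts through the volume chain, corrects for percent recovery, and
#' classifies detection status on the corrected concentration (switchable to
#' the uncorrected scale).
#'
#' @param responses Summed areas, one per replicate injection (IS-normalized
#'   if the curve was fitted on normalized responses).
#' @param curve A valid [fit_standard_addition()] curve.
#' @param chain A [volume_chain()].
#' @param recovery A [percent_recovery()] / [assumed_recovery()] estimate, or
#'   a bare percent value.
#' @param thresholds Optional [compute_lod_loq()] thresholds (concentration
#'   scale) for status classification.
#' @param subloq Optional [evaluate_subloq()] result.
#' @param sample_id Label carried in the result.
#' @param classify_on `"corrected"` (default) or `"uncorrected"`: which scale
#'   the nd/nq classification uses.
#' @return One-row tibble (`quant_result`): `sample_id`, `compound`,
#'   `on_column_fmol`, `conc_uncorrected`, `recovery_used`, `recovery_assumed`,
#'   `conc_corrected`, `status`, `injection_replicates`, `replicate_sd` (on the
#'   corrected-concentration scale, `NA` for a single injection).
#' @export
quantify_sample <- function(responses, curve, chain, recovery = 100,
                            thresholds = NULL, subloq = NULL,
                            sample_id = NA_character_,
                            classify_on = c("corrected", "uncorrected")) {
  classify_on <- match.arg(classify_on)
  if (length(responses) < 1) stop_invalid("Need at least one injection response.")
  rec_pct <- if (inherits(recovery, "recovery_estimate")) recovery$percent_recovery else recovery
  rec_assumed <- if (inherits(recovery, "recovery_estimate")) recovery$assumed else FALSE
  amounts <- response_to_amount(responses, curve)
  fmol <- mean(amounts$fmol)
  conc_unc <- on_column_to_sample_conc(fmol, chain)
  conc_cor <- apply_recovery(conc_unc, rec_pct)
  per_inj_cor <- apply_recovery(on_column_to_sample_conc(amounts$fmol, chain), rec_pct)
  rep_sd <- if (length(responses) >= 2) stats::sd(per_inj_cor) else NA_real_
  status <- NA_character_
  if (!is.null(thresholds)) {
    status <- classify_detection(
      if (classify_on == "corrected") conc_cor else conc_unc,
      thresholds, subloq
    )
  }
  tibble::tibble(
    sample_id = sample_id,
    compound = curve$compound,
    on_column_fmol = fmol,
    conc_uncorrected = conc_unc,
    recovery_used = rec_pct,
    recovery_assumed = rec_assumed,
    conc_corrected = conc_cor,
    status = status,
    injection_replicates = length(responses),
    replicate_sd = rep_sd
  )
}
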