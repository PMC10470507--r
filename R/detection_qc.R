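# LOD/LOQ thresholds, the four-criterion sub-LOQ acceptance rule, and
# spike-based percent recovery.

#' Blank-based limits of detection and quantification
#'
#' Following the blank-based recommendation of standard environmental-chemistry
#' data-quality guidelines: `LOD = mean(blank) + 3 sd(blank)` and
#' `LOQ = mean(blank) + 10 sd(blank)` on the amount scale, then expressed as
#' in-sample concentrations through the volume chain. An alternative,
#' calibration-based variant (`3 * residual_sd / slope` and `10 * ...`) is
#' selectable for curves with well-characterised residuals.
#'
#' @param blank_amounts >= 3 blank determinations, fmol on column.
#' @param chain A [volume_chain()] converting on-column fmol to pM, or `NULL`
#'   to keep thresholds on the fmol scale.
#' @param method `"blank"` (default) or `"calibration"`.
#' @param curve Required for `method = "calibration"`: a [fit_standard_addition()]
#'   curve supplying `residual_sd` and `slope`.
#' @param compound,matrix_group Optional labels.
#' @return A `thresholds` object: `lod`, `loq` (concentration units when a
#'   chain is given, else fmol), `blank_mean`, `blank_sd` (fmol), `n_blanks`.
#' @export
#' @examples
#' compute_lod_loq(c(-1, 1, 3))  # lod 7, loq 21 on the fmol scale
compute_lod_loq <- function(blank_amounts, chain = NULL,
                            method = c("blank", "calibration"), curve = NULL,
                            compound = NA_character_, matrix_group = NA_character_) {
  method <- match.arg(method)
  if (length(blank_amounts) < 3) {
    stop_invalid("Need at least 3 blank determinations for LOD/LOQ.")
  }
  m <- mean(blank_amounts)
  s <- stats::sd(blank_amounts)
  if (method == "blank") {
    lod_fmol <- m + 3 * s
    loq_fmol <- m + 10 * s
  } else {
    if (is.null(curve) || !inherits(curve, "cal_curve") || !curve$valid) {
      stop_invalid("Calibration-based LOD/LOQ needs a valid cal_curve.")
    }
    lod_fmol <- 3 * curve$residual_sd / curve$slope
    loq_fmol <- 10 * curve$residual_sd / curve$slope
  }
  lod_fmol <- max(0, lod_fmol)
  loq_fmol <- max(lod_fmol, loq_fmol)
  to_conc <- function(x) if (is.null(chain)) x else on_column_to_sample_conc(x, chain)
  structure(
    list(
      compound = compound,
      matrix_group = matrix_group,
      lod = to_conc(lod_fmol),
      loq = to_conc(loq_fmol),
      lod_fmol = lod_fmol,
      loq_fmol = loq_fmol,
      blank_mean = m,
      blank_sd = s,
      n_blanks = length(blank_amounts),
      method = method
    ),
    class = "thresholds"
  )
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("<thresholds> %s [%s]: LOD %.4g, LOQ %.4g (%s method, %d blanks)\n",
              x$compound, x$matrix_group, x$lod, x$loq, x$method, x$n_blanks))
  invisible(x)
}

#' Evaluate the four sub-LOQ acceptance criteria
#'
#' A concentration falling between LOD and LOQ is reportable only when all
#' four hold: (i) the candidate peak's retention time matches the authentic
#' standard within `rt_tolerance`; (ii) at least two daughter fragments are
#' present with co-occurring peaks (apexes within `rt_tolerance` of each
#' other); (iii) the fragments appear in the same order of intensity as in the
#' authentic standard (ties within 5% relative area are order-compatible);
#' (iv) the summed peak area is at least twice the average blank area in the
#' retention-time window.
#'
#' @param candidate_areas Area table rows (one injection, one compound) with
#'   `fragment_index`, `area`, `apex_time`.
#' @param standard_areas Same columns for the authentic standard (>= 2
#'   fragments); required.
#' @param blank_mean_area Mean summed blank area in the window.
#' @param rt_tolerance Minutes (default 0.2).
#' @return A `subloq_evaluation`: the four flags and `accepted` (their
#'   conjunction).
#' @export
evaluate_subloq <- function(candidate_areas, standard_areas, blank_mean_area,
                            rt_tolerance = 0.2) {
  if (is.null(standard_areas) || nrow(standard_areas) < 2) {
    stop_invalid("Sub-LOQ evaluation needs an authentic standard with >= 2 fragments.")
  }
  cand <- candidate_areas[order(candidate_areas$fragment_index), ]
  std <- standard_areas[order(standard_areas$fragment_index), ]

  # (i) retention-time match, judged on the strongest candidate fragment
  # against the same fragment of the standard
  top <- cand$fragment_index[which.max(cand$area)]
  std_top <- std[std$fragment_index == top, ]
  rt_match <- nrow(std_top) == 1 &&
    abs(cand$apex_time[cand$fragment_index == top] - std_top$apex_time) <= rt_tolerance

  # (ii) two daughter fragments present with co-occurring peaks
  present <- cand[cand$area > 0, ]
  cooccur <- FALSE
  if (nrow(present) >= 2) {
    cooccur <- (max(present$apex_time) - min(present$apex_time)) <= rt_tolerance
  }

  # (iii) fragment intensity order matches the standard, 5% relative ties OK
  shared <- intersect(cand$fragment_index, std$fragment_index)
  order_match <- FALSE
  if (length(shared) >= 2) {
    a <- cand$area[match(shared, cand$fragment_index)]
    b <- std$area[match(shared, std$fragment_index)]
    ord <- order(-b)
    a <- a[ord]
    order_match <- TRUE
    for (k in seq_len(length(a) - 1)) {
      rel_tie <- abs(a[k] - a[k + 1]) <= 0.05 * max(a[k], a[k + 1])
      if (a[k] < a[k + 1] && !rel_tie) {
        order_match <- FALSE
        break
      }
    }
  }

  # (iv) summed area at least twice the mean blank area
  exceeds_blank <- sum(cand$area) >= 2 * blank_mean_area

  subloq_evaluation(isTRUE(rt_match), isTRUE(cooccur), isTRUE(order_match),
                    isTRUE(exceeds_blank))
}

#' Construct a sub-LOQ evaluation from its four flags
#'
#' `accepted` is the conjunction of all four criteria; there is no partial
#' credit.
#'
#' @param rt_match,two_fragments_cooccur,intensity_order_match,area_exceeds_2x_blank
#'   Logical flags for criteria (i)-(iv).
#' @return A `subloq_evaluation` object.
#' @export
subloq_evaluation <- function(rt_match, two_fragments_cooccur,
                              intensity_order_match, area_exceeds_2x_blank) {
  flags <- c(rt_match, two_fragments_cooccur, intensity_order_match,
             area_exceeds_2x_blank)
  if (!is.logical(flags) || length(flags) != 4 || anyNA(flags)) {
    stop_invalid("All four sub-LOQ flags must be TRUE or FALSE.")
  }
  structure(
    list(
      rt_match = rt_match,
      two_fragments_cooccur = two_fragments_cooccur,
      intensity_order_match = intensity_order_match,
      area_exceeds_2x_blank = area_exceeds_2x_blank,
      accepted = all(flags)
    ),
    class = "subloq_evaluation"
  )
}

#' Percent recovery from a spiked/unspiked sample pair
#'
#' `recovery = 100 * (measured_spiked - endogenous) / spike_amount`, the
#' fraction of a known spike surviving extraction and measurement. Values
#' outside \[10%, 150%\] are flagged suspect.
#'
#' @param measured_spiked Measured concentration in the spiked sample.
#' @param endogenous Measured concentration in the matching unspiked sample.
#' @param spike_amount Added concentration (> 0), same units.
#' @param compound,matrix_group Optional labels.
#' @return A `recovery_estimate`: inputs, `percent_recovery`, `suspect`,
#'   `assumed` (FALSE here; see [assumed_recovery()]).
#' @export
#' @examples
#' percent_recovery(220, 20, 400)  # 50%
percent_recovery <- function(measured_spiked, endogenous, spike_amount,
                             compound = NA_character_, matrix_group = NA_character_) {
  if (!is_scalar_number(spike_amount) || spike_amount <= 0) {
    stop_invalid("`spike_amount` must be positive.")
  }
  pr <- 100 * (measured_spiked - endogenous) / spike_amount
  structure(
    list(
      compound = compound,
      matrix_group = matrix_group,
      spike_amount = spike_amount,
      endogenous = endogenous,
      measured_spiked = measured_spiked,
      percent_recovery = pr,
      suspect = pr < 10 || pr > 150,
      assumed = FALSE
    ),
    class = "recovery_estimate"
  )
}

#' Assert a recovery value without a spike pair
#'
#' When no spiked/unspiked pair exists for a matrix, a recovery established
#' elsewhere may be asserted (the study assumes 50% for FAMP across SPE
#' methods, based on its consistency). Such assertions are flagged `assumed`
#' in all outputs.
#'
#' @param percent Asserted percent recovery in (0, 200].
#' @param compound,matrix_group Optional labels.
#' @return A `recovery_estimate` with `assumed = TRUE`.
#' @export
assumed_recovery <- function(percent, compound = NA_character_,
                             matrix_group = NA_character_) {
  if (!is_scalar_number(percent) || percent <= 0 || percent > 200) {
    stop_invalid("Asserted recovery must lie in (0, 200].")
  }
  structure(
    list(
      compound = compound, matrix_group = matrix_group,
      spike_amount = NA_real_, endogenous = NA_real_,
      measured_spiked = NA_real_, percent_recovery = percent,
      suspect = percent < 10 || percent > 150, assumed = TRUE
    ),
    class = "recovery_estimate"
  )
}

#' @export
print.recovery_estimate <- function(x, ...) {
  cat(sprintf("<recovery_estimate> %s [%s]: %.1f%%%s%s\n",
              x$compound, x$matrix_group, x$percent_recovery,
              if (x$suspect) " (suspect)" else "",
              if (x$assumed) " (assumed)" else ""))
  invisible(x)
}

#' Classify a concentration against detection thresholds
#'
#' `conc >= LOQ` is `quantified`; `LOD <= conc < LOQ` is `reported_subloq`
#' when the sub-LOQ evaluation accepted the peak, otherwise `nq`
#' (present below LOQ); `conc < LOD` is `nd` (below detection).
#'
#' @param conc Concentration, same units as the thresholds.
#' @param thresholds A [compute_lod_loq()] result.
#' @param subloq Optional [evaluate_subloq()] result for the same measurement.
#' @return One of `"quantified"`, `"reported_subloq"`, `"nq"`, `"nd"`.
#' @export
classify_detection <- function(conc, thresholds, subloq = NULL) {
  if (!inherits(thresholds, "thresholds")) stop_invalid("`thresholds` required.")
  if (conc >= thresholds$loq) return("quantified")
  if (conc >= thresholds$lod) {
    if (!is.null(subloq) && isTRUE(subloq$accepted)) return("reported_subloq")
    return("nq")
  }
  "nd"
}
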