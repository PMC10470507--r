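# Matrix-matched standard-addition calibration and internal-standard
# normalization.

#' Decide whether to normalize to the heavy internal standard
#'
#' Some peaks benefit from normalization to the co-injected heavy-labelled
#' internal standard (it cancels injection-volume and source variability);
#' others do not. Following the study's rule, normalization is adopted for a
#' compound only when the relative standard deviation (RSD) of the
#' area / IS-area ratios across replicate QC-pool injections is strictly
#' smaller than the RSD of the raw areas.
#'
#' @param qc_areas Numeric vector of raw analyte areas over replicate QC-pool
#'   injections (>= 3 for a decision).
#' @param qc_is_areas Matching internal-standard areas, same injections.
#' @param compound Optional compound label carried in the result.
#' @return A `normalization_decision`: list with `compound`, `rsd_raw`,
#'   `rsd_normalized`, `normalize`.
#' @export
decide_is_normalization <- function(qc_areas, qc_is_areas, compound = NA_character_) {
  if (length(qc_areas) != length(qc_is_areas)) {
    stop_invalid("Analyte and internal-standard areas must pair by injection.")
  }
  rsd <- function(x) stats::sd(x) / mean(x)
  if (length(qc_areas) < 3) {
    rlang::warn("Fewer than 3 QC replicates; defaulting to no normalization.")
    return(structure(
      list(compound = compound, rsd_raw = NA_real_, rsd_normalized = NA_real_,
           normalize = FALSE),
      class = "normalization_decision"
    ))
  }
  rsd_raw <- rsd(qc_areas)
  rsd_norm <- rsd(qc_areas / qc_is_areas)
  structure(
    list(compound = compound, rsd_raw = rsd_raw, rsd_normalized = rsd_norm,
         normalize = rsd_norm < rsd_raw),
    class = "normalization_decision"
  )
}

#' @export
print.normalization_decision <- function(x, ...) {
  cat(sprintf("<normalization_decision> %s: raw RSD %.3g, IS-ratio RSD %.3g -> %s\n",
              x$compound, x$rsd_raw, x$rsd_normalized,
              if (isTRUE(x$normalize)) "normalize" else "no normalization"))
  invisible(x)
}

#' Fit a standard-addition calibration line
#'
#' Ordinary least squares of response (summed peak area, optionally
#' IS-normalized) on the added standard amount. Replicate injections enter as
#' individual points. The x-intercept magnitude, `intercept / slope`, estimates
#' the endogenous on-column amount of the calibration matrix (the QC pool).
#' A non-positive slope flags the curve invalid; downstream quantification
#' refuses invalid curves.
#'
#' @param added_fmol Added amounts, fmol; >= 3 distinct levels including 0.
#' @param responses Responses paired with `added_fmol`.
#' @param compound,matrix_group Optional labels carried in the result.
#' @param weights `"none"` (default) or `"1/x"` (zero-addition points get the
#'   smallest non-zero level's weight).
#' @return A `cal_curve`: `slope`, `intercept`, `r_squared`, `residual_sd`,
#'   `endogenous_fmol`, `valid`, labels, and `used_is_normalization` (set by
#'   the pipeline).
#' @export
#' @examples
#' fit_standard_addition(c(0, 25, 50, 250), c(100, 600, 1100, 5100))
fit_standard_addition <- function(added_fmol, responses,
                                  compound = NA_character_,
                                  matrix_group = NA_character_,
                                  weights = c("none", "1/x")) {
  weights <- match.arg(weights)
  if (length(added_fmol) != length(responses)) {
    stop_invalid("`added_fmol` and `responses` must have equal length.")
  }
  lev <- sort(unique(added_fmol))
  if (length(lev) < 3 || !any(lev == 0)) {
    rlang::abort("Standard addition needs >= 3 distinct levels including 0.",
                 class = "srmquant_invalid_design")
  }
  w <- NULL
  if (weights == "1/x") {
    x0 <- min(lev[lev > 0])
    w <- 1 / pmax(added_fmol, x0)
  }
  fit <- stats::lm(responses ~ added_fmol, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  valid <- is.finite(slope) && slope > 0
  structure(
    list(
      compound = compound,
      matrix_group = matrix_group,
      slope = slope,
      intercept = intercept,
      r_squared = r2,
      residual_sd = stats::sigma(fit),
      endogenous_fmol = if (valid) max(0, intercept / slope) else NA_real_,
      valid = valid,
      used_is_normalization = FALSE,
      n_points = length(responses)
    ),
    class = "cal_curve"
  )
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve> %s [%s]%s\n", x$compound, x$matrix_group,
              if (x$valid) "" else " (INVALID)"))
  cat(sprintf("  slope %.4g area/fmol, intercept %.4g, r2 %.5f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  endogenous %.4g fmol on column; %d points%s\n",
              x$endogenous_fmol, x$n_points,
              if (x$used_is_normalization) "; IS-normalized" else ""))
  invisible(x)
}

#' Convert a response to an on-column amount
#'
#' Default (slope-only) mode divides the response by the calibration slope;
#' the matrix-matched slope carries the quantification while the curve's
#' intercept reflects the QC pool's endogenous level, a property of the pool
#' rather than of the sample. An optional blank-subtraction mode subtracts a
#' blank response first. Negative amounts clamp to 0 and are flagged
#' below-blank.
#'
#' @param response Numeric vector of summed areas (IS-normalized if the curve
#'   was fitted on normalized responses).
#' @param curve A valid [fit_standard_addition()] curve.
#' @param blank_response Optional blank response to subtract (default 0).
#' @return Tibble: `response`, `fmol`, `below_blank`.
#' @export
response_to_amount <- function(response, curve, blank_response = 0) {
  if (!inherits(curve, "cal_curve")) stop_invalid("`curve` must be a cal_curve.")
  if (!curve$valid) {
    rlang::abort("Refusing to quantify with an invalid calibration curve.",
                 class = "srmquant_invalid_curve")
  }
  raw <- (response - blank_response) / curve$slope
  tibble::tibble(
    response = response,
    fmol = pmax(0, raw),
    below_blank = raw <= 0
  )
}
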