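#' Targeted-compound specification
#'
#' A `compound_spec` describes one SRM target: its precursor m/z, the ordered
#' product-ion (fragment) m/z values with their relative intensities, the
#' expected retention time and Gaussian peak width, and whether the compound is
#' an analyte or a heavy-labelled internal standard.
#'
#' @param name Compound identifier (e.g. `"FAMP"`).
#' @param precursor_mz Precursor mass-to-charge (Th).
#' @param fragment_mzs Numeric vector of fragment m/z values (Th), ordered.
#' @param fragment_rel_intensities Relative fragment intensities, same order as
#'   `fragment_mzs`; strictly positive and summing to 1.
#' @param retention_time Apex retention time in minutes; must lie inside the
#'   chromatographic run (`run_span`).
#' @param peak_sigma Gaussian peak standard deviation in minutes.
#' @param role `"analyte"` or `"heavy_internal_standard"`.
#' @param run_span Length-2 numeric giving the run start/end in minutes used to
#'   validate `retention_time` (default 0--12 min).
#' @return An object of class `compound_spec`.
#' @export
#' @examples
#' compound_spec("FAMP", 167.1, c(122.1, 150.1), c(0.6, 0.4), 2.6)
compound_spec <- function(name, precursor_mz, fragment_mzs,
                          fragment_rel_intensities, retention_time,
                          peak_sigma = 0.05, role = c("analyte", "heavy_internal_standard"),
                          run_span = c(0, 12)) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_invalid("`name` must be a non-empty string.")
  }
  check_positive_scalar(precursor_mz, "precursor_mz")
  if (!is.numeric(fragment_mzs) || length(fragment_mzs) < 1L) {
    stop_invalid("`fragment_mzs` must be a non-empty numeric vector.")
  }
  if (length(fragment_rel_intensities) != length(fragment_mzs)) {
    stop_invalid("`fragment_rel_intensities` must pair with `fragment_mzs`.")
  }
  if (any(fragment_rel_intensities <= 0)) {
    stop_invalid("Fragment relative intensities must be strictly positive.")
  }
  if (abs(sum(fragment_rel_intensities) - 1) > 1e-9) {
    stop_invalid("Fragment relative intensities must sum to 1 (within 1e-9).")
  }
  if (role == "analyte" && length(fragment_mzs) < 2L) {
    stop_invalid("Analytes need at least 2 fragment transitions (sub-LOQ criterion ii).")
  }
  check_positive_scalar(peak_sigma, "peak_sigma")
  if (!is_scalar_number(retention_time) ||
      retention_time <= run_span[1] || retention_time >= run_span[2]) {
    stop_invalid("`retention_time` must lie inside the run span.")
  }
  structure(
    list(
      name = name,
      precursor_mz = precursor_mz,
      fragment_mzs = as.numeric(fragment_mzs),
      fragment_rel_intensities = as.numeric(fragment_rel_intensities),
      retention_time = retention_time,
      peak_sigma = peak_sigma,
      role = role
    ),
    class = "compound_spec"
  )
}

#' @export
print.compound_spec <- function(x, ...) {
  cat(sprintf("<compound_spec> %s (%s)\n", x$name, x$role))
  cat(sprintf("  precursor m/z %.1f; RT %.2f min (sigma %.3f min)\n",
              x$precursor_mz, x$retention_time, x$peak_sigma))
  cat(sprintf("  fragments: %s\n",
              paste(sprintf("%.1f (%.0f%%)", x$fragment_mzs,
                            100 * x$fragment_rel_intensities),
                    collapse = ", ")))
  invisible(x)
}

#' Default thiamin-vitamer SRM panel
#'
#' Returns the seven-compound panel used throughout the package: thiamin (B1),
#' the pyrimidine vitamers HMP, AmMP and FAMP, the thiazole vitamers cHET and
#' HET, and a 13C-labelled heavy thiamin internal standard that co-elutes with
#' B1. The m/z and retention-time constants are synthetic fixture values chosen
#' to be plausible for this chemistry; they are configuration, not reference
#' data, and every downstream function accepts user-supplied panels.
#'
#' @return Named list of [compound_spec()] objects, one of which has role
#'   `heavy_internal_standard`. Deterministic: repeated calls are identical.
#' @export
#' @examples
#' panel <- make_default_panel()
#' names(panel)
make_default_panel <- function() {
  specs <- list(
    compound_spec("B1", 265.1, c(122.1, 144.0, 81.1), c(0.55, 0.30, 0.15),
                  retention_time = 5.8, peak_sigma = 0.05),
    compound_spec("HMP", 140.1, c(122.1, 81.1), c(0.70, 0.30),
                  retention_time = 1.9, peak_sigma = 0.04),
    compound_spec("AmMP", 139.1, c(122.1, 81.1), c(0.60, 0.40),
                  retention_time = 1.5, peak_sigma = 0.04),
    compound_spec("FAMP", 167.1, c(122.1, 150.1, 81.1), c(0.50, 0.30, 0.20),
                  retention_time = 2.6, peak_sigma = 0.05),
    compound_spec("cHET", 145.0, c(127.0, 112.0), c(0.65, 0.35),
                  retention_time = 3.4, peak_sigma = 0.05),
    compound_spec("HET", 144.1, c(126.0, 112.0), c(0.60, 0.40),
                  retention_time = 4.2, peak_sigma = 0.05),
    compound_spec("B1_13C", 269.1, c(126.1, 148.0, 85.1), c(0.55, 0.30, 0.15),
                  retention_time = 5.8, peak_sigma = 0.05,
                  role = "heavy_internal_standard")
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}
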