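# Peak integration and quantifier-transition selection.
#
# Integration replaces the study's interactive Skyline step with a
# parameter-free rule: linear baseline between the window edges, trapezoidal
# integration of the residual, negative areas clamped to zero.

#' Integration window around an expected retention time
#'
#' @param center Window centre, minutes (usually the compound retention time).
#' @param half_width Half-width, minutes (default 0.2, the retention-time
#'   tolerance used by the sub-LOQ acceptance rule).
#' @return An `integration_window` object.
#' @export
integration_window <- function(center, half_width = 0.2) {
  check_positive_scalar(half_width, "half_width")
  if (!is_scalar_number(center)) stop_invalid("`center` must be a number.")
  structure(list(center = center, half_width = half_width),
            class = "integration_window")
}

# Validate a single-fragment trace and return it ordered by time.
as_trace <- function(trace) {
  if (!all(c("time_min", "intensity") %in% names(trace))) {
    stop_invalid("A trace needs `time_min` and `intensity` columns.")
  }
  trace <- trace[order(trace$time_min), , drop = FALSE]
  if (any(diff(trace$time_min) <= 0)) {
    stop_invalid("Trace time grid must be strictly increasing.")
  }
  trace
}

#' Integrate one SRM peak
#'
#' Subtracts a linear baseline interpolated between the intensities at the two
#' window edges, integrates the residual with the trapezoidal rule, and clamps
#' negative results to zero. The apex is the maximum of the baseline-corrected
#' signal inside the window.
#'
#' @param trace Data frame with `time_min` and `intensity` for one fragment.
#' @param window An [integration_window()], fully inside the trace span.
#' @return A one-row tibble: `area` (intensity·min), `apex_time`,
#'   `apex_intensity` (baseline-corrected).
#' @export
integrate_peak <- function(trace, window) {
  trace <- as_trace(trace)
  lo <- window$center - window$half_width
  hi <- window$center + window$half_width
  if (lo < min(trace$time_min) || hi > max(trace$time_min)) {
    rlang::abort("Integration window falls outside the trace span.",
                 class = "srmquant_invalid_window")
  }
  inside <- trace$time_min >= lo & trace$time_min <= hi
  t_w <- trace$time_min[inside]
  y_w <- trace$intensity[inside]
  if (length(t_w) < 3) {
    rlang::abort("Integration window contains fewer than 3 points.",
                 class = "srmquant_invalid_window")
  }
  # linear baseline between the window-edge intensities
  base <- y_w[1] + (y_w[length(y_w)] - y_w[1]) *
    (t_w - t_w[1]) / (t_w[length(t_w)] - t_w[1])
  resid <- y_w - base
  area <- max(0, pracma::trapz(t_w, resid))
  apex_i <- which.max(resid)
  tibble::tibble(
    area = area,
    apex_time = t_w[apex_i],
    apex_intensity = max(0, resid[apex_i])
  )
}

#' Signal-to-noise ratio of a peak
#'
#' Defined as the baseline-corrected apex intensity divided by a robust noise
#' scale: 1.4826 × the median absolute deviation of the out-of-window
#' intensities about their median. Returns `Inf` when the noise estimate is 0
#' (noise-free traces).
#'
#' @inheritParams integrate_peak
#' @return Numeric scalar (possibly `Inf`).
#' @export
signal_to_noise <- function(trace, window) {
  trace <- as_trace(trace)
  lo <- window$center - window$half_width
  hi <- window$center + window$half_width
  outside <- trace$time_min < lo | trace$time_min > hi
  if (sum(outside) < 20) {
    stop_invalid("Need at least 20 points outside the window for a noise estimate.")
  }
  noise <- stats::mad(trace$intensity[outside])  # 1.4826 * MAD by default
  pk <- integrate_peak(trace, window)
  if (noise == 0) return(Inf)
  pk$apex_intensity / noise
}

#' Integrate every (injection, compound, fragment) peak in a batch
#'
#' Convenience wrapper applying [integrate_peak()] and [signal_to_noise()]
#' across a long-format trace table, windowing each compound at its panel
#' retention time.
#'
#' @param traces Tibble with `injection_id`, `compound`, `fragment_index`,
#'   `time_min`, `intensity` (as produced by [simulate_batch()] or
#'   [read_traces()]).
#' @param panel Named list of [compound_spec()]s giving retention times.
#' @param half_width Window half-width in minutes (default 0.2).
#' @return Tibble: `injection_id`, `compound`, `fragment_index`, `area`,
#'   `apex_time`, `apex_intensity`, `snr`.
#' @export
integrate_batch <- function(traces, panel, half_width = 0.2) {
  keys <- dplyr::distinct(traces, .data$injection_id, .data$compound,
                          .data$fragment_index)
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    cmp <- panel[[k$compound]]
    if (is.null(cmp)) stop_invalid(sprintf("Compound `%s` missing from panel.", k$compound))
    tr <- traces[traces$injection_id == k$injection_id &
                   traces$compound == k$compound &
                   traces$fragment_index == k$fragment_index, ]
    win <- integration_window(cmp$retention_time, half_width)
    pk <- integrate_peak(tr, win)
    pk$snr <- signal_to_noise(tr, win)
    rows[[i]] <- dplyr::bind_cols(k, pk)
  }
  dplyr::bind_rows(rows)
}

#' Select quantifier transitions per compound
#'
#' Scores every fragment transition by mean signal-to-noise over calibration
#' injections, penalised by blank interference
#' (`score = mean_snr / (1 + interference)` with
#' `interference = mean blank area / mean lowest-nonzero-level area`), and
#' picks the top-scoring fragment as quantifier. Ties break deterministically
#' on the lower `fragment_index`. All fragments are retained (as qualifiers)
#' for identity checks. Without blank injections the score falls back to
#' signal-to-noise only, with a warning.
#'
#' @param cal_areas Area table ([integrate_batch()] output) for calibration
#'   injections, with an `added_fmol` column giving each injection's added
#'   standard amount.
#' @param blank_areas Area table for blank injections, or `NULL`.
#' @return Tibble: `compound`, `fragment_index`, `score`, `quantifier` (flag).
#' @export
select_quantifier_transitions <- function(cal_areas, blank_areas = NULL) {
  if (nrow(cal_areas) == 0) stop_invalid("Need at least one calibration injection.")
  if (is.null(blank_areas) || nrow(blank_areas) == 0) {
    rlang::warn("No blank injections supplied; scoring by signal-to-noise only.")
    blank_areas <- NULL
  }
  scores <- lapply(split(cal_areas, cal_areas$compound), function(ca) {
    cmp <- ca$compound[1]
    # mean area at the lowest non-zero addition level, per fragment
    nz <- ca[!is.na(ca$added_fmol) & ca$added_fmol > 0, ]
    low_level <- if (nrow(nz)) min(nz$added_fmol) else NA_real_
    per_frag <- lapply(split(ca, ca$fragment_index), function(fa) {
      frag <- fa$fragment_index[1]
      mean_snr <- mean(ifelse(is.infinite(fa$snr), .Machine$double.xmax, fa$snr))
      interference <- 0
      if (!is.null(blank_areas)) {
        ba <- blank_areas[blank_areas$compound == cmp &
                            blank_areas$fragment_index == frag, ]
        low <- fa[!is.na(fa$added_fmol) & fa$added_fmol == low_level, ]
        if (nrow(ba) && nrow(low) && mean(low$area) > 0) {
          interference <- mean(ba$area) / mean(low$area)
        }
      }
      tibble::tibble(compound = cmp, fragment_index = frag,
                     score = mean_snr / (1 + interference))
    })
    out <- dplyr::bind_rows(per_frag)
    out <- out[order(-out$score, out$fragment_index), ]
    out$quantifier <- seq_len(nrow(out)) == 1L
    out[order(out$fragment_index), ]
  })
  dplyr::bind_rows(scores)
}

#' Sum peak areas of the chosen fragments for one injection
#'
#' @param areas Area table rows belonging to a single (injection, compound).
#' @return Scalar summed area.
#' @export
summed_area <- function(areas) {
  if (nrow(areas) == 0) stop_invalid("No areas supplied.")
  if (length(unique(areas$injection_id)) > 1 || length(unique(areas$compound)) > 1) {
    stop_invalid("`summed_area` expects areas from one injection and one compound.")
  }
  sum(areas$area)
}
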