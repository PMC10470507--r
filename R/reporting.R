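# Study-style result rendering: replicate summaries, nd/nq strings and
# dissolved-phase mass balances with propagated uncertainty.

#' Summarize replicate measurements
#'
#' Mean always; sample standard deviation (n-1 denominator) only when the
#' measurements come from at least 3 independent replicates — technical
#' duplicates of a single sample carry no SD, matching the study tables'
#' convention.
#'
#' @param values Numeric measurements (>= 1).
#' @param n_independent Number of independent replicates behind them
#'   (default `length(values)`).
#' @param units Unit label (e.g. `"nM"`), used for mass-balance unit checks.
#' @param digits Significant figures for the display string (default 2).
#' @return A `summary_value`: `mean`, `sd` (`NA` when `n_independent < 3`),
#'   `n`, `units`, `display` (e.g. `"18 ± 11"`).
#' @export
#' @examples
#' summarize_replicates(c(1, 2, 3))          # mean 2, sd 1
#' summarize_replicates(c(5, 7), n_independent = 1)  # mean 6, no sd
summarize_replicates <- function(values, n_independent = length(values),
                                 units = NA_character_, digits = 2) {
  if (length(values) < 1) stop_invalid("Need at least one value to summarize.")
  m <- mean(values)
  s <- if (n_independent >= 3) stats::sd(values) else NA_real_
  summary_value(m, s, n = n_independent, units = units, digits = digits)
}

#' Construct a summary value directly from a mean and SD
#'
#' @param mean Mean concentration.
#' @param sd Standard deviation, or `NA` when not reportable.
#' @param n Number of independent replicates.
#' @param units Unit label.
#' @param digits Significant figures for display.
#' @return A `summary_value` object.
#' @export
summary_value <- function(mean, sd = NA_real_, n = NA_integer_,
                          units = NA_character_, digits = 2) {
  disp <- if (is.na(sd)) {
    format_sigfig(mean, digits)
  } else {
    paste0(format_sigfig(mean, digits), " ± ", format_sigfig(sd, digits))
  }
  structure(
    list(mean = mean, sd = sd, n = n, units = units, display = disp,
         digits = digits),
    class = "summary_value"
  )
}

#' @export
print.summary_value <- function(x, ...) {
  cat(sprintf("<summary_value> %s%s (n = %s)\n", x$display,
              if (is.na(x$units)) "" else paste0(" ", x$units), x$n))
  invisible(x)
}

#' Dissolved-phase concentration change with uncertainty
#'
#' The spent-minus-blank mass balance: `delta = spent_mean - blank_mean`, with
#' uncertainty propagated either in quadrature (`sqrt(s1^2 + s2^2)`, the
#' default) or as the plain sum (`s1 + s2`); both modes are kept because
#' published budget tables are sometimes consistent with one and sometimes the
#' other.
#'
#' @param spent,blank [summary_value()]s in the same units.
#' @param mode `"quadrature"` (default) or `"sum"`.
#' @param digits Significant figures for display (default 2).
#' @return A `mass_balance`: `delta_mean`, `delta_uncertainty`,
#'   `propagation_mode`, `display`, plus the inputs.
#' @export
#' @examples
#' sp <- summary_value(57, 9.8, 3, "nM")
#' bl <- summary_value(39, 1.6, 3, "nM")
#' dissolved_phase_change(sp, bl, mode = "sum")$display  # "18 ± 11"
dissolved_phase_change <- function(spent, blank, mode = c("quadrature", "sum"),
                                   digits = 2) {
  mode <- match.arg(mode)
  if (!inherits(spent, "summary_value") || !inherits(blank, "summary_value")) {
    stop_invalid("`spent` and `blank` must be summary_value objects.")
  }
  if (!is.na(spent$units) && !is.na(blank$units) && spent$units != blank$units) {
    stop_invalid("Spent and blank summaries must share units.")
  }
  delta <- spent$mean - blank$mean
  s1 <- if (is.na(spent$sd)) 0 else spent$sd
  s2 <- if (is.na(blank$sd)) 0 else blank$sd
  u <- if (mode == "quadrature") sqrt(s1^2 + s2^2) else s1 + s2
  structure(
    list(
      spent = spent,
      blank = blank,
      delta_mean = delta,
      delta_uncertainty = u,
      propagation_mode = mode,
      units = spent$units,
      display = paste0(format_sigfig(delta, digits), " ± ",
                       format_sigfig(u, digits))
    ),
    class = "mass_balance"
  )
}

#' @export
print.mass_balance <- function(x, ...) {
  cat(sprintf("<mass_balance> change %s%s (%s mode)\n", x$display,
              if (is.na(x$units)) "" else paste0(" ", x$units),
              x$propagation_mode))
  invisible(x)
}

# Display string for one quant_result row.
result_cell <- function(mean, sd, status, digits = 2) {
  if (is.na(status) || status %in% c("quantified", "reported_subloq")) {
    cell <- if (is.na(sd)) format_sigfig(mean, digits) else
      paste0(format_sigfig(mean, digits), " ± ", format_sigfig(sd, digits))
    if (identical(status, "reported_subloq")) cell <- paste0(cell, "*") # below LOQ
    return(cell)
  }
  status  # "nd" / "nq"
}

#' Render a study-style result table
#'
#' One row per (sample, compound), deterministically ordered. Quantified and
#' accepted sub-LOQ results show `mean ± sd` at `digits` significant figures
#' (sub-LOQ values marked `*`); below-LOD is `"nd"`, unaccepted below-LOQ is
#' `"nq"`, and compounds never measured for a sample render `"X"`.
#'
#' @param results Tibble of [quantify_sample()] rows (a `replicate_sd` column
#'   supplies the ± term; `NA` suppresses it).
#' @param balances Optional named list of [dissolved_phase_change()] objects
#'   appended as extra rows (sample id `"Change in dissolved phase"`).
#' @param compounds Optional character vector fixing column order; compounds
#'   absent from a sample's results render `"X"`.
#' @param digits Significant figures (default 2).
#' @return A `report` object: list with `table` (wide tibble of display
#'   strings) and `text` (aligned character lines).
#' @export
render_report <- function(results, balances = NULL, compounds = NULL,
                          digits = 2) {
  if (is.null(compounds)) compounds <- sort(unique(results$compound))
  samples <- sort(unique(results$sample_id))
  rows <- lapply(samples, function(sid) {
    cells <- vapply(compounds, function(cmp) {
      r <- results[results$sample_id == sid & results$compound == cmp, ]
      if (nrow(r) == 0) return("X")
      result_cell(r$conc_corrected[1], r$replicate_sd[1], r$status[1], digits)
    }, character(1))
    tibble::as_tibble(c(list(sample = sid), as.list(cells)))
  })
  tab <- dplyr::bind_rows(rows)
  if (!is.null(balances)) {
    cells <- vapply(compounds, function(cmp) {
      b <- balances[[cmp]]
      if (is.null(b)) "X" else b$display
    }, character(1))
    tab <- dplyr::bind_rows(
      tab, tibble::as_tibble(c(list(sample = "Change in dissolved phase"),
                               as.list(cells)))
    )
  }
  widths <- vapply(names(tab), function(nm) {
    max(nchar(nm, type = "width"), nchar(tab[[nm]], type = "width"))
  }, numeric(1))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  header <- paste(mapply(pad, names(tab), widths), collapse = "  ")
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    paste(mapply(pad, unlist(tab[i, ]), widths), collapse = "  ")
  }, character(1))
  structure(list(table = tab, text = c(header, lines)), class = "report")
}

#' @export
print.report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
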