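# Internal helpers shared across modules.

#' @importFrom rlang abort warn
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never clobbers user RNG.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(msg, class = "srmquant_invalid_input") {
  rlang::abort(msg, class = class)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

#' Format a number to a fixed number of significant figures
#'
#' Plain (never scientific) formatting that keeps significant trailing zeros,
#' matching the style of study result tables (e.g. `11.4 -> "11"`,
#' `0.027 -> "0.027"`, `-20.3 -> "-20"`).
#'
#' @param x Numeric vector.
#' @param digits Significant figures (default 2).
#' @return Character vector.
#' @export
#' @examples
#' format_sigfig(c(11.4, 0.027, -20.3))
format_sigfig <- function(x, digits = 2) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == 0) return("0")
    out <- formatC(signif(v, digits), digits = digits, format = "fg", flag = "#")
    out <- sub("\\.$", "", out)
    # formatC(flag = "#") can pad with trailing zeros beyond `digits` for
    # large magnitudes; trim only a bare trailing dot, keep e.g. "0.50".
    out
  }, character(1))
}
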