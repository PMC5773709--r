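# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed without touching global RNG state
#'
#' All stochastic generators in the package route through this helper so that
#' fixtures are pure functions of their parameters plus a seed.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a base-pair count in kilobases or megabases
#'
#' Values are rounded half away from zero to two decimals, the convention used
#' for all Kbp/Mbp figures reported by the package. The raw base-pair count
#' should always be kept alongside the formatted value.
#'
#' @param bp Number of base pairs.
#' @param unit `"Kbp"` or `"Mbp"`.
#' @return Numeric value in the requested unit, rounded to two decimals.
#' @examples
#' format_bp(176460, "Kbp")   # 176.46
#' format_bp(3042857, "Mbp")  # 3.04
#' @export
format_bp <- function(bp, unit = c("Kbp", "Mbp")) {
  unit <- match.arg(unit)
  div <- if (unit == "Kbp") 1e3 else 1e6
  round_half_away(bp / div, 2L)
}

# Single scalar non-empty string check.
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
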