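#' Round half away from zero
#'
#' Commercial rounding as used throughout the costing tables: ties go away
#' from zero (`769.5` -> `770`), unlike [base::round()]'s round-half-even.
#' Values are first snapped to 6 decimals past the target digit so that
#' binary representation artifacts (e.g. `85500 * 0.009 = 769.4999...`)
#' cannot push an exact tie below the rounding boundary.
#'
#' @param x Numeric vector.
#' @param digits Integer; decimal places to keep (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_away(769.5)   # 770
#' round_half_away(1154.25) # 1154
#' round_half_away(11.577, 1)
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(round(abs(x) * p, 6) + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean calendar month length in days; used when a phase duration in days
# must be expressed as an age increment in months
DAYS_PER_MONTH <- 30.4375

is_true <- function(x) !is.na(x) & x
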