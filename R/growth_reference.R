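#' Load an LMS growth-reference table
#'
#' Reads a CSV with columns `indicator` (`weight_for_age` or
#' `weight_for_height`), `sex` (`male`/`female`), `index` (age in completed
#' months for weight-for-age, height/length in cm for weight-for-height) and
#' the LMS parameters `L`, `M`, `S`.  The schema matches the WHO Child Growth
#' Standards expanded tables, so real WHO tables are drop-in replacements for
#' the bundled synthetic fixture.
#'
#' @param path Path to the reference CSV.
#' @return A tibble of class `growth_reference`.
#' @seealso [ncp_growth_reference()] for the bundled table, [compute_z()].
#' @export
load_growth_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_growth_reference(ref)
}

#' Coerce a data frame to a validated growth reference
#'
#' @param ref Data frame with columns `indicator`, `sex`, `index`, `L`, `M`, `S`.
#' @return A tibble of class `growth_reference`.
#' @export
as_growth_reference <- function(ref) {
  needed <- c("indicator", "sex", "index", "L", "M", "S")
  missing_cols <- setdiff(needed, names(ref))
  if (length(missing_cols) > 0) {
    stop("growth reference lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ref) == 0) stop("growth reference table is empty", call. = FALSE)
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    stop("growth reference requires M > 0 and S > 0", call. = FALSE)
  }
  split_idx <- split(ref$index, paste(ref$indicator, ref$sex))
  ok <- vapply(split_idx, function(x) all(diff(x) > 0), logical(1))
  if (!all(ok)) {
    stop("growth reference index values must be strictly increasing within ",
         "each (indicator, sex) group", call. = FALSE)
  }
  out <- tibble::as_tibble(ref[needed])
  class(out) <- c("growth_reference", class(out))
  out
}

#' Bundled synthetic growth-reference table
#'
#' A smooth synthetic LMS table covering weight-for-age (6-180 months) and
#' weight-for-height (65-120 cm) for both sexes.  It has realistic magnitudes
#' but is not the WHO standard; substitute real WHO tables via
#' [load_growth_reference()] for clinical use.
#'
#' @return A `growth_reference` tibble.
#' @export
ncp_growth_reference <- function() {
  path <- system.file("extdata", "growth_reference_synthetic.csv",
                      package = "ncpcost", mustWork = TRUE)
  load_growth_reference(path)
}

# Interpolate L, M, S at index values for one (indicator, sex) stratum.
# Linear interpolation in the index variable; outside the tabulated range is
# an error (never extrapolated).
lms_params <- function(reference, indicator, sex, index_value) {
  sub <- reference[reference$indicator == indicator & reference$sex == sex, ]
  if (nrow(sub) == 0) {
    stop("no growth-reference rows for indicator '", indicator,
         "', sex '", sex, "'", call. = FALSE)
  }
  rng <- range(sub$index)
  bad <- !is.na(index_value) & (index_value < rng[1] | index_value > rng[2])
  if (any(bad)) {
    stop(sprintf("index value %s outside %s reference range [%s, %s]",
                 index_value[bad][1], indicator, rng[1], rng[2]), call. = FALSE)
  }
  list(
    L = stats::approx(sub$index, sub$L, xout = index_value, rule = 1)$y,
    M = stats::approx(sub$index, sub$M, xout = index_value, rule = 1)$y,
    S = stats::approx(sub$index, sub$S, xout = index_value, rule = 1)$y
  )
}

lms_value_at <- function(L, M, S, z) {
  ifelse(abs(L) < 1e-12, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

#' Compute an LMS z-score
#'
#' Box-Cox (LMS) z-score `z = ((X/M)^L - 1) / (L * S)` with L, M, S linearly
#' interpolated between the bracketing reference rows, and the WHO
#' restricted-z adjustment applied beyond |z| = 3: extreme scores are
#' expressed as distance past the +/-3 SD bound in units of the outermost
#' 1-SD gap, which keeps the far tails linear in the measurement.
#'
#' @param indicator `"weight_for_age"` or `"weight_for_height"`.
#' @param sex `"male"` or `"female"` (recycled across values).
#' @param index_value Age in months (weight-for-age) or height in cm
#'   (weight-for-height); vectorised.
#' @param measurement_kg Weight in kg (> 0); vectorised. `NA` propagates to
#'   an `NA` z-score (a missing measurement is data, not an error).
#' @param reference A `growth_reference` table.
#' @return Numeric vector of z-scores.
#' @examples
#' ref <- ncp_growth_reference()
#' compute_z("weight_for_age", "male", 12, 9.6, ref)
#' @export
compute_z <- function(indicator, sex, index_value, measurement_kg,
                      reference = ncp_growth_reference()) {
  indicator <- match.arg(indicator, c("weight_for_age", "weight_for_height"))
  if (any(!is.na(measurement_kg) & measurement_kg <= 0)) {
    stop("measurement_kg must be > 0", call. = FALSE)
  }
  n <- max(length(index_value), length(measurement_kg), length(sex))
  index_value <- rep_len(index_value, n)
  measurement_kg <- rep_len(measurement_kg, n)
  sex <- rep_len(sex, n)

  z <- rep(NA_real_, n)
  for (sx in unique(sex[!is.na(measurement_kg)])) {
    sel <- which(sex == sx & !is.na(measurement_kg) & !is.na(index_value))
    if (length(sel) == 0) next
    p <- lms_params(reference, indicator, sx, index_value[sel])
    z[sel] <- lms_z(measurement_kg[sel], p$L, p$M, p$S)
  }
  z
}

# core LMS transform + WHO restricted-z tail adjustment
lms_z <- function(x, L, M, S) {
  z0 <- ifelse(abs(L) < 1e-12,
               log(x / M) / S,
               ((x / M)^L - 1) / (L * S))
  sd2p <- lms_value_at(L, M, S, 2);  sd3p <- lms_value_at(L, M, S, 3)
  sd2n <- lms_value_at(L, M, S, -2); sd3n <- lms_value_at(L, M, S, -3)
  ifelse(z0 > 3, 3 + (x - sd3p) / (sd3p - sd2p),
  ifelse(z0 < -3, -3 + (x - sd3n) / (sd2n - sd3n), z0))
}

#' Invert a z-score to a measurement
#'
#' Returns the weight (kg) that [compute_z()] maps to the requested z-score,
#' including inversion of the restricted-z tail adjustment.  Used by the
#' synthetic cohort generator to back-compute weights from sampled z-scores.
#'
#' @inheritParams compute_z
#' @param z Target z-score; vectorised.
#' @return Numeric vector of measurements in kg.
#' @export
measurement_for_z <- function(indicator, sex, index_value, z,
                              reference = ncp_growth_reference()) {
  indicator <- match.arg(indicator, c("weight_for_age", "weight_for_height"))
  n <- max(length(index_value), length(z), length(sex))
  index_value <- rep_len(index_value, n)
  z <- rep_len(z, n)
  sex <- rep_len(sex, n)

  out <- rep(NA_real_, n)
  for (sx in unique(sex[!is.na(z)])) {
    sel <- which(sex == sx & !is.na(z) & !is.na(index_value))
    if (length(sel) == 0) next
    p <- lms_params(reference, indicator, sx, index_value[sel])
    zz <- z[sel]
    sd2p <- lms_value_at(p$L, p$M, p$S, 2);  sd3p <- lms_value_at(p$L, p$M, p$S, 3)
    sd2n <- lms_value_at(p$L, p$M, p$S, -2); sd3n <- lms_value_at(p$L, p$M, p$S, -3)
    out[sel] <- ifelse(zz > 3, sd3p + (zz - 3) * (sd3p - sd2p),
               ifelse(zz < -3, sd3n + (zz + 3) * (sd2n - sd3n),
                      lms_value_at(p$L, p$M, p$S, zz)))
  }
  out
}
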