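#' MUAC screening against age-banded cutoffs
#'
#' Mid-upper arm circumference below the severe-acute-malnutrition cutoff for
#' the child's age band: < 115 mm at 6-60 months, < 129 mm at 5-9 years and
#' < 160 mm at 10-14 years.  The comparison is strictly less-than, so a
#' measurement exactly at the cutoff does not screen positive.
#'
#' @param age_months Age in months, within `[6, 179]`; vectorised.
#' @param muac_mm MUAC in mm (> 0); `NA` returns `NA`.
#' @return Logical vector.
#' @examples
#' muac_below_cutoff(24, 110)  # TRUE
#' muac_below_cutoff(24, 115)  # FALSE (strict inequality)
#' @export
muac_below_cutoff <- function(age_months, muac_mm) {
  n <- max(length(age_months), length(muac_mm))
  age_months <- rep_len(age_months, n)
  muac_mm <- rep_len(muac_mm, n)
  if (any(!is.na(age_months) & (age_months < 6 | age_months > 179))) {
    stop("age_months must be within [6, 179] for MUAC screening", call. = FALSE)
  }
  if (any(!is.na(muac_mm) & muac_mm <= 0)) {
    stop("muac_mm must be > 0", call. = FALSE)
  }
  cutoff <- ifelse(age_months < 61, 115, ifelse(age_months < 120, 129, 160))
  muac_mm < cutoff
}

#' Weight-loss and growth-flattening flags from visit history
#'
#' Compares the two most recent weights: confirmed weight loss means a drop
#' of more than 5% since the previous visit; growth-curve flattening means
#' zero or negative change that does not reach the 5% loss threshold.  With
#' fewer than two visits both flags are returned as `NA` (not evaluable).
#'
#' @param visit_weights Data frame with columns `date` (coercible to
#'   [Date][base::Dates]) and `weight_kg`, one row per visit.
#' @return List with logical scalars `confirmed_weight_loss` and
#'   `growth_curve_flattening` (possibly `NA`).
#' @export
assess_weight_history <- function(visit_weights) {
  na <- list(confirmed_weight_loss = NA, growth_curve_flattening = NA)
  if (is.null(visit_weights) || NROW(visit_weights) < 2) return(na)
  stopifnot(all(c("date", "weight_kg") %in% names(visit_weights)))
  dates <- as.Date(visit_weights$date)
  if (any(diff(as.numeric(dates)) < 0)) {
    stop("visit dates must be chronological", call. = FALSE)
  }
  k <- nrow(visit_weights)
  w_prev <- visit_weights$weight_kg[k - 1]
  w_last <- visit_weights$weight_kg[k]
  if (is.na(w_prev) || is.na(w_last)) return(na)
  loss <- (w_prev - w_last) / w_prev > 0.05
  list(
    confirmed_weight_loss = loss,
    growth_curve_flattening = !loss && (w_last - w_prev) <= 0
  )
}

#' Assess one child's anthropometric status
#'
#' Computes WAZ (and WHZ/MUAC status where measured), the severe acute
#' malnutrition (SAM) flag and the moderate-undernutrition flag from the
#' measurements that are actually present.  SAM is positive on any of:
#' WHZ < -3, MUAC below the age cutoff, visible severe wasting, or bilateral
#' pedal oedema.  Moderate undernutrition is WAZ <= -2 or WHZ <= -2 without
#' SAM (strict `<` variant available via `inclusive_moderate = FALSE`).
#' Indicators whose inputs are absent are reported missing, never silently
#' defaulted, and the absences are listed in `missing_fields`.
#'
#' @param record One child record: a list or one-row data frame with fields
#'   `age_months`, `sex`, and optionally `weight_kg`, `height_cm`, `muac_mm`,
#'   `visible_wasting`, `bilateral_pedal_oedema`, `visit_weights`.
#' @param reference A `growth_reference` table.
#' @param inclusive_moderate Use `<= -2` (default) or strict `< -2` for the
#'   moderate-undernutrition z threshold.
#' @return List of class `anthro_assessment`: `waz`, `whz`,
#'   `muac_below_cutoff`, `sam`, `moderate_undernutrition`,
#'   `confirmed_weight_loss`, `growth_curve_flattening`, `missing_fields`.
#' @export
assess_child <- function(record, reference = ncp_growth_reference(),
                         inclusive_moderate = TRUE) {
  rec <- as.list(record)
  get <- function(f) {
    v <- rec[[f]]
    if (is.null(v) || length(v) == 0) NA else v
  }
  age <- get("age_months")
  sex <- get("sex")
  if (is.na(age)) stop("record needs age_months", call. = FALSE)

  missing_fields <- character()
  weight <- get("weight_kg")
  height <- get("height_cm")
  muac <- get("muac_mm")

  waz <- NA_real_
  if (is.na(weight)) {
    missing_fields <- c(missing_fields, "weight_kg")
  } else {
    waz <- compute_z("weight_for_age", sex, age, weight, reference)
  }
  whz <- NA_real_
  if (is.na(height) || is.na(weight)) {
    missing_fields <- c(missing_fields, "height_cm")
  } else {
    whz <- compute_z("weight_for_height", sex, height, weight, reference)
  }
  muac_low <- NA
  if (is.na(muac)) {
    missing_fields <- c(missing_fields, "muac_mm")
  } else {
    muac_low <- muac_below_cutoff(age, muac)
  }
  wasting <- get("visible_wasting")
  oedema <- get("bilateral_pedal_oedema")
  if (is.na(wasting)) missing_fields <- c(missing_fields, "visible_wasting")
  if (is.na(oedema)) missing_fields <- c(missing_fields, "bilateral_pedal_oedema")

  hist <- assess_weight_history(rec[["visit_weights"]])

  sam <- is_true(whz < -3) || is_true(muac_low) ||
    is_true(wasting) || is_true(oedema)

  thr <- function(z) if (inclusive_moderate) z <= -2 else z < -2
  moderate <- if (sam) {
    FALSE
  } else if (is.na(waz) && is.na(whz)) {
    NA  # no anthropometry at all: moderate undernutrition is not evaluable
  } else {
    is_true(thr(waz)) || is_true(thr(whz))
  }

  structure(
    list(
      waz = waz, whz = whz, muac_below_cutoff = muac_low,
      sam = sam, moderate_undernutrition = moderate,
      confirmed_weight_loss = hist$confirmed_weight_loss,
      growth_curve_flattening = hist$growth_curve_flattening,
      missing_fields = unique(missing_fields)
    ),
    class = "anthro_assessment"
  )
}
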