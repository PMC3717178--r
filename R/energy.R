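#' Default supplemental-energy table
#'
#' Daily additional energy by age band and care plan, as in the WHO
#' chart-booklet recommendations: NCP-B as an absolute kcal/day range
#' (weight-independent), NCP-C as a total kcal/kg/day range of which a
#' configurable fraction (default half) is supplied as supplementation.
#' The five bands tile ages 6-179 months without overlap.
#'
#' @return Tibble with columns `band`, `lo_months`, `hi_months`,
#'   `b_lower`, `b_upper` (kcal/day), `c_lower`, `c_upper` (kcal/kg/day).
#' @export
default_energy_tables <- function() {
  tibble::tibble(
    band = c("6-11 months", "12-23 months", "2-5 years", "6-9 years",
             "10-14 years"),
    lo_months = c(6, 12, 24, 72, 120),
    hi_months = c(11, 23, 71, 119, 179),
    b_lower = c(120, 160, 200, 260, 340),
    b_upper = c(150, 190, 280, 380, 400),
    c_lower = c(150, 150, 150, 75, 60),
    c_upper = c(220, 220, 220, 100, 90)
  )
}

#' Energy policy
#'
#' Which bound of the recommended daily intake range to cost (the published
#' analysis uses the upper bound — 30% additional intake for NCP-B, 100% for
#' NCP-C — to compensate for household food insecurity) and the fraction of
#' the NCP-C total daily requirement supplied as supplementation.
#'
#' @param bound `"upper"` (default) or `"lower"`.
#' @param ncp_c_supplement_fraction Fraction in (0, 1]; default 0.5 (the
#'   other half is assumed to come from household provision).
#' @return List of class `energy_policy`.
#' @export
energy_policy <- function(bound = c("upper", "lower"),
                          ncp_c_supplement_fraction = 0.5) {
  bound <- match.arg(bound)
  stopifnot(ncp_c_supplement_fraction > 0, ncp_c_supplement_fraction <= 1)
  structure(list(bound = bound,
                 ncp_c_supplement_fraction = ncp_c_supplement_fraction),
            class = "energy_policy")
}

band_index <- function(age_months, tables = default_energy_tables()) {
  if (any(is.na(age_months)) ||
      any(age_months < min(tables$lo_months) | age_months > max(tables$hi_months))) {
    stop("age_months outside the energy-table range [",
         min(tables$lo_months), ", ", max(tables$hi_months), "]", call. = FALSE)
  }
  findInterval(age_months, tables$lo_months)
}

#' Age band for energy requirements
#'
#' @param age_months Age in months within the table range; vectorised.
#' @param tables Energy table as from [default_energy_tables()].
#' @return Character vector of band labels.
#' @examples
#' age_band(c(7, 23, 24, 179))
#' @export
age_band <- function(age_months, tables = default_energy_tables()) {
  tables$band[band_index(age_months, tables)]
}

#' Daily supplemental energy for NCP-B
#'
#' Weight-independent kcal/day by age band (upper bound: 150/190/280/380/400;
#' lower: 120/160/200/260/340).
#'
#' @inheritParams age_band
#' @param policy An [energy_policy()].
#' @return Numeric vector, kcal/day.
#' @export
ncp_b_daily_kcal <- function(age_months, policy = energy_policy(),
                             tables = default_energy_tables()) {
  i <- band_index(age_months, tables)
  if (policy$bound == "upper") tables$b_upper[i] else tables$b_lower[i]
}

#' Daily supplemental energy for NCP-C
#'
#' The total daily requirement is weight-based (kcal/kg/day by age band);
#' the returned supplement amount is that total times the policy's
#' supplementation fraction (default half, the remainder from household
#' food).
#'
#' @inheritParams ncp_b_daily_kcal
#' @param weight_kg Weight in kg (> 0).
#' @return Numeric vector, kcal/day supplied as supplementation.
#' @examples
#' ncp_c_daily_supplement_kcal(18, 10)  # 10 kg x 220 kcal/kg x 0.5 = 1100
#' @export
ncp_c_daily_supplement_kcal <- function(age_months, weight_kg,
                                        policy = energy_policy(),
                                        tables = default_energy_tables()) {
  stopifnot(all(weight_kg > 0))
  i <- band_index(age_months, tables)
  rate <- if (policy$bound == "upper") tables$c_upper[i] else tables$c_lower[i]
  weight_kg * rate * policy$ncp_c_supplement_fraction
}
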