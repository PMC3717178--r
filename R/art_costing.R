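#' First-line paediatric ART regimens with 26-week drug costs
#'
#' Two regimens by age: abacavir + lamivudine + lopinavir/ritonavir in
#' liquid formulation for children aged 3 years or under, and abacavir +
#' lamivudine + efavirenz in tablet form for older children, costed per
#' child for 26 weeks at the mean weight of each age group (2010 South
#' African DoH prices).  Mean group weights are carried as metadata; dosing
#' arithmetic is embedded in the per-drug costs.
#'
#' @param young_costs Named numeric: 26-week per-child ZAR costs for the
#'   `<=3 y` regimen (default ABC 907, 3TC 767, LPV/r 667).
#' @param old_costs Named numeric for the `>3 y` regimen (default ABC 2274,
#'   3TC 304, EFV 757).
#' @param mean_weights_kg Metadata: mean weight per group (default 9.8, 21.6).
#' @return Tibble with one row per regimen (`group`, `max_age_months`,
#'   `drugs` list-column, `cost_per_child_zar`, `mean_weight_kg`).
#' @export
art_regimens <- function(young_costs = c(ABC = 907, `3TC` = 767, `LPV/r` = 667),
                         old_costs = c(ABC = 2274, `3TC` = 304, EFV = 757),
                         mean_weights_kg = c(9.8, 21.6)) {
  stopifnot(all(young_costs > 0), all(old_costs > 0))
  tibble::tibble(
    group = c("<=3 years", ">3 years"),
    max_age_months = c(36, 179),
    drugs = list(young_costs, old_costs),
    cost_per_child_zar = c(sum(young_costs), sum(old_costs)),
    mean_weight_kg = mean_weights_kg
  )
}

#' Regimen for a child's age
#'
#' Liquid-formulation regimen up to and including 36 months, tablet regimen
#' above.
#'
#' @param age_months Age in months within `[6, 179]`.
#' @param regimens From [art_regimens()].
#' @return One-row tibble (the matching regimen).
#' @export
regimen_for_age <- function(age_months, regimens = art_regimens()) {
  if (any(age_months < 6 | age_months > 179)) {
    stop("age_months outside [6, 179]", call. = FALSE)
  }
  regimens[ifelse(age_months <= 36, 1L, 2L), ]
}

#' Cohort ART cost over 26 weeks
#'
#' @param n_young Number of children aged <= 3 years.
#' @param n_old Number of children aged > 3 years.
#' @param regimens From [art_regimens()].
#' @param fx USD per ZAR.
#' @return List of class `art_cost`: `by_group` tibble and `total_zar`,
#'   `total_usd`.
#' @examples
#' cohort_art_cost(92, 159)$total_zar  # 745,637
#' @export
cohort_art_cost <- function(n_young, n_old, regimens = art_regimens(),
                            fx = exchange_rate()) {
  stopifnot(n_young >= 0, n_old >= 0)
  by_group <- tibble::tibble(
    group = regimens$group,
    n = c(n_young, n_old),
    cost_per_child_zar = regimens$cost_per_child_zar,
    cost_zar = regimens$cost_per_child_zar * c(n_young, n_old)
  )
  total <- sum(by_group$cost_zar)
  structure(list(by_group = by_group, total_zar = total,
                 total_usd = round_half_away(total * fx)),
            class = "art_cost")
}

#' Supplement cost as a percentage of ART cost
#'
#' `100 * supplement / (art_26wk * horizon/26)`, reported to one decimal.
#' Supplementation is needed at most once per year while ART runs
#' continuously, so the 52-week horizon halves the percentage.
#'
#' @param supplement_zar Supplement cost, ZAR.
#' @param art_zar_26wk 26-week ART cost, ZAR (> 0).
#' @param horizon_weeks ART horizon in weeks (26 or 52).
#' @return Percentage, rounded to 1 decimal.
#' @examples
#' proportional_cost(86324, 745637, 26)  # 11.6
#' proportional_cost(86324, 745637, 52)  # 5.8
#' @export
proportional_cost <- function(supplement_zar, art_zar_26wk,
                              horizon_weeks = 26) {
  if (art_zar_26wk <= 0) stop("ART cost must be > 0", call. = FALSE)
  stopifnot(horizon_weeks > 0)
  round_half_away(100 * supplement_zar / (art_zar_26wk * horizon_weeks / 26), 1)
}
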