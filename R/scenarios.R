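#' Define a duration-sensitivity scenario
#'
#' Clinical experience suggests many children reach exit criteria before 26
#' weeks (moderate undernutrition by ~12 weeks, SAM by 12-16 weeks), so the
#' base costing can be rescaled with shorter supplementation durations.
#' Durations may be stratified by TB status for the NCP-B-only group, since
#' children on TB treatment keep supplementation until treatment completes.
#'
#' @param name Scenario label.
#' @param ncp_b_weeks NCP-B-only group duration, weeks (default 26).
#' @param sam_c_weeks SAM stabilisation duration, weeks (default 10).
#' @param sam_b_weeks SAM rehabilitation duration, weeks (default 16).
#' @param ncp_b_weeks_tb,ncp_b_weeks_non_tb Optional TB-stratified NCP-B
#'   durations; when set they replace `ncp_b_weeks` and require stratified
#'   base costs.
#' @param notes Free-text note.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(name, ncp_b_weeks = 26, sam_c_weeks = 10,
                          sam_b_weeks = 16, ncp_b_weeks_tb = NULL,
                          ncp_b_weeks_non_tb = NULL, notes = NULL) {
  stopifnot(ncp_b_weeks > 0, sam_c_weeks > 0, sam_b_weeks > 0)
  structure(list(name = name, ncp_b_weeks = ncp_b_weeks,
                 sam_c_weeks = sam_c_weeks, sam_b_weeks = sam_b_weeks,
                 ncp_b_weeks_tb = ncp_b_weeks_tb,
                 ncp_b_weeks_non_tb = ncp_b_weeks_non_tb, notes = notes),
            class = "scenario_spec")
}

#' Rescale an aggregate cost to a new duration
#'
#' Costs are linear in duration, so a group's cost over a different
#' supplementation period is the base cost scaled by the duration ratio and
#' rounded to whole ZAR.
#'
#' @param base_cost_zar Base aggregate cost, ZAR.
#' @param base_weeks Duration the base cost covers (> 0).
#' @param new_weeks New duration (> 0).
#' @return Whole-ZAR cost.
#' @examples
#' scale_cost(45414, 26, 12)  # 20,960
#' @export
scale_cost <- function(base_cost_zar, base_weeks, new_weeks) {
  if (base_weeks <= 0 || new_weeks <= 0) {
    stop("durations must be > 0", call. = FALSE)
  }
  round_half_away(base_cost_zar * new_weeks / base_weeks)
}

# Extract the base aggregates run_scenario() needs from a cohort cost
# summary (plus the ART comparator).
scenario_base <- function(cost_summary, art_zar_26wk,
                          fx = cost_summary$fx %||% exchange_rate()) {
  t <- cost_summary$totals
  base <- list(ncp_b_zar = t$ncp_b_zar, sam_c_zar = t$sam_c_zar,
               sam_b_zar = t$sam_b_zar, art_zar_26wk = art_zar_26wk, fx = fx)
  cc <- cost_summary$child_costs
  if (!is.null(cc) && !all(is.na(cc$prevalent_tb[cc$plan == "B"]))) {
    b <- cc[cc$plan == "B", ]
    base$ncp_b_zar_tb <- sum(b$cost_zar[is_true(b$prevalent_tb)])
    base$ncp_b_zar_non_tb <- sum(b$cost_zar[!is_true(b$prevalent_tb)])
  }
  base
}

#' Re-cost the cohort under a scenario
#'
#' Applies per-group duration scaling to the base aggregate costs (matching
#' the published sensitivity arithmetic, which rescales printed totals
#' rather than re-deriving per-child courses), sums, converts to USD and
#' recomputes the 26- and 52-week proportional costs against ART.
#'
#' @param spec A [scenario_spec()].
#' @param base Either a `cohort_cost_summary` (then `art_zar_26wk` must be
#'   given) or a list with `ncp_b_zar`, `sam_c_zar`, `sam_b_zar`,
#'   `art_zar_26wk`, optionally `ncp_b_zar_tb`/`ncp_b_zar_non_tb` and `fx`.
#' @param art_zar_26wk 26-week ART comparator cost (when `base` is a cost
#'   summary).
#' @param base_weeks Durations the base costs cover: list with `ncp_b`,
#'   `sam_c`, `sam_b` in weeks (defaults 26/10/16).
#' @return List of class `scenario_result`: component costs, `total_zar`,
#'   `total_usd`, `pct_26wk`, `pct_52wk`.
#' @examples
#' base <- list(ncp_b_zar = 45414, sam_c_zar = 33245, sam_b_zar = 7665,
#'              art_zar_26wk = 745637)
#' run_scenario(scenario_spec("early exit", 12, 10, 6), base)$total_zar  # 57,079
#' @export
run_scenario <- function(spec, base, art_zar_26wk = NULL,
                         base_weeks = list(ncp_b = 26, sam_c = 10, sam_b = 16)) {
  if (inherits(base, "cohort_cost_summary")) {
    if (is.null(art_zar_26wk)) {
      stop("art_zar_26wk is required with a cohort_cost_summary base",
           call. = FALSE)
    }
    base <- scenario_base(base, art_zar_26wk)
  }
  fx <- base$fx %||% exchange_rate()

  stratified <- !is.null(spec$ncp_b_weeks_tb) || !is.null(spec$ncp_b_weeks_non_tb)
  if (stratified) {
    if (is.null(base$ncp_b_zar_tb) || is.null(base$ncp_b_zar_non_tb)) {
      stop("TB-stratified scenario needs TB-stratified base costs ",
           "(ncp_b_zar_tb / ncp_b_zar_non_tb); TB flags were missing",
           call. = FALSE)
    }
    b_cost <- scale_cost(base$ncp_b_zar_tb, base_weeks$ncp_b,
                         spec$ncp_b_weeks_tb %||% spec$ncp_b_weeks) +
      scale_cost(base$ncp_b_zar_non_tb, base_weeks$ncp_b,
                 spec$ncp_b_weeks_non_tb %||% spec$ncp_b_weeks)
  } else {
    b_cost <- scale_cost(base$ncp_b_zar, base_weeks$ncp_b, spec$ncp_b_weeks)
  }
  sam_c <- scale_cost(base$sam_c_zar, base_weeks$sam_c, spec$sam_c_weeks)
  sam_b <- scale_cost(base$sam_b_zar, base_weeks$sam_b, spec$sam_b_weeks)
  total <- b_cost + sam_c + sam_b

  structure(list(
    name = spec$name,
    ncp_b_zar = b_cost, sam_c_zar = sam_c, sam_b_zar = sam_b,
    sam_zar = sam_c + sam_b,
    total_zar = total,
    total_usd = round_half_away(total * fx),
    pct_26wk = proportional_cost(total, base$art_zar_26wk, 26),
    pct_52wk = proportional_cost(total, base$art_zar_26wk, 52)
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s': ZAR%s ($%s); %s%% of 26-wk ART, %s%% of 52-wk ART\n",
              x$name, format(x$total_zar, big.mark = ","),
              format(x$total_usd, big.mark = ","), x$pct_26wk, x$pct_52wk))
  invisible(x)
}
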