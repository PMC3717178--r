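#' NCP-B exit decision
#'
#' A child can step down from NCP-B to NCP-A (supplementation discontinued)
#' once all three hold: the latest WAZ or WHZ is above -1; weight increased
#' strictly over a run of at least two consecutive visits whose first and
#' last dates are at least 30 days apart; and any condition with increased
#' energy needs (e.g. ongoing TB treatment) has resolved.
#'
#' @param visits Data frame of follow-up visits, chronological, with columns
#'   `date`, `weight_kg` and optionally `waz`, `whz`.
#' @param comorbidity_present Does the child have a qualifying comorbidity?
#' @param comorbidity_resolved Has it resolved (`NA` = unknown)?
#' @return List with `exit` (logical, `NA` if not evaluable) and `reason`.
#' @export
ncp_b_exit <- function(visits, comorbidity_present = FALSE,
                       comorbidity_resolved = NA) {
  if (NROW(visits) < 2) {
    return(list(exit = NA, reason = "insufficient visit history"))
  }
  dates <- as.Date(visits$date)
  if (any(diff(as.numeric(dates)) < 0)) {
    stop("visit dates must be chronological", call. = FALSE)
  }
  z_last <- function(col) {
    v <- visits[[col]]
    if (is.null(v)) return(NA_real_)
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else v[length(v)]
  }
  waz <- z_last("waz"); whz <- z_last("whz")
  z_ok <- is_true(waz > -1) || is_true(whz > -1)
  if (!z_ok) return(list(exit = FALSE, reason = "z-score not above -1"))

  gain_ok <- sustained_gain(dates, visits$weight_kg, min_days = 30)
  if (!gain_ok) {
    return(list(exit = FALSE,
                reason = "no sustained weight gain over >=2 visits spanning >=30 days"))
  }
  if (comorbidity_present && !is_true(comorbidity_resolved)) {
    return(list(exit = FALSE, reason = "comorbidity not resolved"))
  }
  list(exit = TRUE, reason = "exit criteria met")
}

# any maximal run of strictly increasing weights with >=2 visits spanning
# >= min_days calendar days
sustained_gain <- function(dates, weights, min_days = 30) {
  n <- length(weights)
  if (n < 2) return(FALSE)
  run_start <- 1
  for (i in 2:n) {
    if (is.na(weights[i]) || is.na(weights[i - 1]) ||
        weights[i] <= weights[i - 1]) {
      run_start <- i
    } else if (as.numeric(dates[i] - dates[run_start]) >= min_days) {
      return(TRUE)
    }
  }
  FALSE
}

#' NCP-C to NCP-B downgrade decision
#'
#' A SAM child moves from stabilisation (NCP-C) to rehabilitation (NCP-B)
#' when: oedema has resolved AND appetite has recovered AND WHZ is at least
#' -1; OR weight has risen 15% above the post-oedema baseline; OR the mean
#' daily weight gain reaches 5 g/kg/day (the floor of the 5-15 g/kg/day
#' in-hospital band, and the single community threshold).
#'
#' @param visits Chronological follow-up visits with `date`, `weight_kg`,
#'   optional `whz`, `oedema` (logical).
#' @param post_oedema_baseline_kg Baseline weight after oedema loss, for the
#'   15%-gain branch (`NULL` if unknown).
#' @param setting `"community"` or `"hospital"`.
#' @param appetite_recovered Logical (`NA` = unknown).
#' @return List with `downgrade` (logical, `NA` if not evaluable) and
#'   `reason`.
#' @export
ncp_c_downgrade <- function(visits, post_oedema_baseline_kg = NULL,
                            setting = c("community", "hospital"),
                            appetite_recovered = NA) {
  setting <- match.arg(setting)
  if (NROW(visits) < 1) {
    return(list(downgrade = NA, reason = "no visits"))
  }
  last <- visits[NROW(visits), ]
  oedema_now <- if ("oedema" %in% names(visits)) last$oedema else NA
  oedema_gone <- !is_true(oedema_now) && !is.na(oedema_now)
  whz <- if ("whz" %in% names(visits)) last$whz else NA_real_

  if (oedema_gone && is_true(appetite_recovered) && is_true(whz >= -1)) {
    return(list(downgrade = TRUE, reason = "oedema lost, appetite recovered, WHZ >= -1"))
  }
  if (oedema_gone && !is.null(post_oedema_baseline_kg) &&
      !is.na(last$weight_kg) &&
      last$weight_kg >= 1.15 * post_oedema_baseline_kg) {
    return(list(downgrade = TRUE, reason = "15% weight gain after oedema loss"))
  }
  if (NROW(visits) >= 2) {
    days <- as.numeric(as.Date(last$date) - as.Date(visits$date[1]))
    w0 <- visits$weight_kg[1]
    if (days > 0 && !is.na(w0) && !is.na(last$weight_kg)) {
      gain_g_kg_day <- (last$weight_kg - w0) * 1000 / w0 / days
      if (gain_g_kg_day >= 5) {
        return(list(downgrade = TRUE,
                    reason = sprintf("gain %.1f g/kg/day >= 5 (%s)",
                                     gain_g_kg_day, setting)))
      }
      return(list(downgrade = FALSE, reason = "criteria not met"))
    }
  }
  if (is.null(post_oedema_baseline_kg) && !is_true(appetite_recovered) &&
      NROW(visits) < 2) {
    return(list(downgrade = NA, reason = "not evaluable"))
  }
  list(downgrade = FALSE, reason = "criteria not met")
}
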