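#' Assign a WHO Nutritional Care Plan
#'
#' Applies the care-plan rules with precedence C > B > A:
#' * **NCP-C** for severe acute malnutrition (any SAM criterion);
#' * **NCP-B** for moderate undernutrition, confirmed weight loss, growth
#'   curve flattening, prevalent TB, another condition with increased
#'   nutritional needs, or WHO clinical stage 3/4;
#' * **NCP-A** when every B trigger is determinably false;
#' * **UNASSIGNED** when no positive trigger fires but a trigger cannot be
#'   ruled out — either no usable anthropometry, or TB/comorbidity/stage all
#'   unrecorded.  A positive trigger always beats missingness elsewhere.
#'
#' @param assessment An `anthro_assessment` from [assess_child()].
#' @param record The child record the assessment was derived from.
#' @param stage_trigger Treat WHO stage 3/4 as an NCP-B trigger (default
#'   `TRUE`).
#' @return List of class `ncp_assignment` with elements `plan` (`"A"`,
#'   `"B"`, `"C"` or `"UNASSIGNED"`) and `reasons` (character vector of
#'   machine-readable codes).
#' @export
assign_ncp <- function(assessment, record, stage_trigger = TRUE) {
  rec <- as.list(record)
  get <- function(f) {
    v <- rec[[f]]
    if (is.null(v) || length(v) == 0) NA else v
  }
  a <- assessment

  if (isTRUE(a$sam)) {
    reasons <- c(
      if (is_true(a$whz < -3)) "SAM_WHZ",
      if (is_true(a$muac_below_cutoff)) "SAM_MUAC",
      if (is_true(get("visible_wasting"))) "SAM_WASTING",
      if (is_true(get("bilateral_pedal_oedema"))) "SAM_OEDEMA"
    )
    return(structure(list(plan = "C", reasons = reasons),
                     class = "ncp_assignment"))
  }

  tb <- get("prevalent_tb")
  com <- get("comorbidity_increased_needs")
  stage <- get("who_stage")
  reasons <- c(
    if (is_true(a$moderate_undernutrition)) "UNDERWEIGHT",
    if (is_true(a$confirmed_weight_loss)) "WEIGHT_LOSS",
    if (is_true(a$growth_curve_flattening)) "FLATTENING",
    if (is_true(tb)) "TB",
    if (is_true(com)) "COMORBIDITY",
    if (stage_trigger && is_true(stage >= 3)) "STAGE_3_4"
  )
  if (length(reasons) > 0) {
    return(structure(list(plan = "B", reasons = reasons),
                     class = "ncp_assignment"))
  }

  morbidity_undetermined <- is.na(tb) && is.na(com) && is.na(stage)
  anthropometry_undetermined <- is.na(a$moderate_undernutrition)
  if (morbidity_undetermined || anthropometry_undetermined) {
    return(structure(list(plan = "UNASSIGNED", reasons = "MISSING_DATA"),
                     class = "ncp_assignment"))
  }
  structure(list(plan = "A", reasons = character()), class = "ncp_assignment")
}

# Fill any absent optional ChildRecord columns with NA so downstream code can
# index uniformly.
complete_record_columns <- function(records) {
  records <- tibble::as_tibble(records)
  opt_num <- c("weight_kg", "height_cm", "muac_mm", "who_stage")
  opt_lgl <- c("visible_wasting", "bilateral_pedal_oedema", "prevalent_tb",
               "comorbidity_increased_needs")
  for (col in opt_num) if (is.null(records[[col]])) records[[col]] <- NA_real_
  for (col in opt_lgl) if (is.null(records[[col]])) records[[col]] <- NA
  if (is.null(records[["sex"]])) records[["sex"]] <- NA_character_
  records
}

validate_cohort <- function(records) {
  if (NROW(records) == 0) stop("cohort is empty", call. = FALSE)
  if (is.null(records$child_id)) stop("cohort needs a child_id column", call. = FALSE)
  dup <- records$child_id[duplicated(records$child_id)]
  if (length(dup) > 0) {
    stop("duplicate child_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(records$age_months) | records$age_months < 6 |
                 records$age_months > 179)
  if (length(bad) > 0) {
    stop("age_months outside [6, 179] (or missing) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(records$weight_kg) & records$weight_kg <= 0)) {
    stop("weight_kg must be > 0 when present", call. = FALSE)
  }
  invisible(records)
}

#' Classify a cohort into Nutritional Care Plans
#'
#' Vectorised assessment and plan assignment for a whole cohort, with
#' per-plan, per-reason and per-age-band tallies.  Children eligible for
#' supplementation are those assigned NCP-B or NCP-C.
#'
#' @param records Cohort tibble/data frame, one row per child, with columns
#'   named as in the child-record schema (`child_id`, `age_months`, `sex`,
#'   optional `weight_kg`, `height_cm`, `muac_mm`, `visible_wasting`,
#'   `bilateral_pedal_oedema`, `prevalent_tb`,
#'   `comorbidity_increased_needs`, `who_stage`, list-column
#'   `visit_weights`).
#' @param reference A `growth_reference` table.
#' @param inclusive_moderate,stage_trigger See [assess_child()] and
#'   [assign_ncp()].
#' @return Object of class `ncp_classification`: a list with
#'   `assignments` (tibble: child_id, age_months, age_band, plan, reasons
#'   list-column, waz, whz, sam), `counts` (named integer vector over
#'   A/B/C/UNASSIGNED), `reason_counts`, `band_counts` (plan x age-band
#'   table), `eligible`, `eligible_pct` (whole percent) and `n`.
#' @examples
#' cl <- classify_cohort(fixture_cohort_2010())
#' cl$counts
#' @export
classify_cohort <- function(records, reference = ncp_growth_reference(),
                            inclusive_moderate = TRUE, stage_trigger = TRUE) {
  records <- complete_record_columns(records)
  validate_cohort(records)
  n <- nrow(records)

  waz <- compute_z("weight_for_age", records$sex, records$age_months,
                   records$weight_kg, reference)
  whz <- rep(NA_real_, n)
  has_h <- !is.na(records$height_cm) & !is.na(records$weight_kg)
  if (any(has_h)) {
    whz[has_h] <- compute_z("weight_for_height", records$sex[has_h],
                            records$height_cm[has_h],
                            records$weight_kg[has_h], reference)
  }
  muac_low <- muac_below_cutoff(records$age_months, records$muac_mm)

  cwl <- rep(NA, n); gcf <- rep(NA, n)
  if ("visit_weights" %in% names(records)) {
    for (i in seq_len(n)) {
      h <- assess_weight_history(records$visit_weights[[i]])
      cwl[i] <- h$confirmed_weight_loss
      gcf[i] <- h$growth_curve_flattening
    }
  }

  sam <- is_true(whz < -3) | is_true(muac_low) |
    is_true(records$visible_wasting) | is_true(records$bilateral_pedal_oedema)
  thr <- if (inclusive_moderate) function(z) z <= -2 else function(z) z < -2
  moderate <- ifelse(sam, FALSE,
              ifelse(is.na(waz) & is.na(whz), NA,
                     is_true(thr(waz)) | is_true(thr(whz))))

  plan <- character(n)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    a <- list(waz = waz[i], whz = whz[i], muac_below_cutoff = muac_low[i],
              sam = sam[i], moderate_undernutrition = moderate[i],
              confirmed_weight_loss = cwl[i], growth_curve_flattening = gcf[i])
    asg <- assign_ncp(a, records[i, , drop = FALSE], stage_trigger = stage_trigger)
    plan[i] <- asg$plan
    reasons[[i]] <- asg$reasons
  }

  plans <- factor(plan, levels = c("A", "B", "C", "UNASSIGNED"))
  band_tab <- default_energy_tables()
  band <- factor(age_band(records$age_months, band_tab),
                 levels = band_tab$band)
  assignments <- tibble::tibble(
    child_id = records$child_id,
    age_months = records$age_months,
    age_band = band,
    plan = plan,
    reasons = reasons,
    waz = waz, whz = whz, sam = sam
  )
  eligible <- sum(plans %in% c("B", "C"))
  structure(
    list(
      assignments = assignments,
      counts = table(plans),
      reason_counts = table(unlist(reasons)),
      band_counts = table(plan = plans, age_band = band),
      eligible = eligible,
      eligible_pct = round_half_away(100 * eligible / n),
      n = n
    ),
    class = "ncp_classification"
  )
}

#' @export
print.ncp_classification <- function(x, ...) {
  cat("NCP classification of", x$n, "children\n")
  print(x$counts)
  cat(sprintf("Eligible for supplementation (B or C): %d/%d (%d%%)\n",
              x$eligible, x$n, x$eligible_pct))
  invisible(x)
}
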