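#' Specification for a synthetic cohort
#'
#' Parameters of the generative model behind [generate_cohort()].  The
#' defaults emulate the composition of a 2010 rural South African paediatric
#' ART-initiation cohort: 251 children aged 6 months to 14 years, SAM
#' prevalence 25/251, prevalent-TB prevalence 44/251, probability ~0.18 of
#' WAZ <= -2 among non-SAM children (normal WAZ with mean -0.95, SD 1.15),
#' other-comorbidity prevalence 0.13587 conditional on no TB, and joint
#' missingness of the TB/comorbidity/stage fields of 0.11335 — calibrated so
#' the expected plan counts are 88 NCP-B, 25 NCP-C, 21 unassigned and 117
#' NCP-A.  Heights and MUAC are fully missing by default, mirroring a
#' programme without stadiometers or tape measures.
#'
#' @param n Cohort size.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param age_band_props Probabilities over the five energy age bands
#'   (default: the deterministic fixture cohort's band proportions).
#' @param waz_mean,waz_sd Normal WAZ parameters for non-SAM children.
#' @param sam_waz_mean,sam_waz_sd WAZ parameters for SAM children.
#' @param sam_prevalence,tb_prevalence Marginal prevalences.
#' @param comorbidity_prevalence P(other comorbidity | no TB).
#' @param missing_morbidity_rate P(TB, comorbidity and stage all unrecorded),
#'   applied jointly and completely at random after generation.
#' @param missing_height_rate,missing_muac_rate,missing_weight_rate
#'   Missing-completely-at-random rates for the measurements.
#' @param oedema_fraction Fraction of SAM presenting with bilateral pedal
#'   oedema (the rest with visible wasting).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 251, seed = NULL,
                        age_band_props = NULL,
                        waz_mean = -0.95, waz_sd = 1.15,
                        sam_waz_mean = -3.3, sam_waz_sd = 0.6,
                        sam_prevalence = 25 / 251,
                        tb_prevalence = 44 / 251,
                        comorbidity_prevalence = 0.13587,
                        missing_morbidity_rate = 0.11335,
                        missing_height_rate = 1,
                        missing_muac_rate = 1,
                        missing_weight_rate = 0,
                        oedema_fraction = 0.15) {
  if (is.null(age_band_props)) {
    age_band_props <- c(25, 34, 65, 53, 74) / 251
  }
  stopifnot(n > 0, length(age_band_props) == 5,
            abs(sum(age_band_props) - 1) < 1e-8,
            all(c(sam_prevalence, tb_prevalence, comorbidity_prevalence,
                  missing_morbidity_rate, missing_height_rate,
                  missing_muac_rate, missing_weight_rate,
                  oedema_fraction) >= 0),
            all(c(sam_prevalence, tb_prevalence, comorbidity_prevalence,
                  missing_morbidity_rate, missing_height_rate,
                  missing_muac_rate, missing_weight_rate,
                  oedema_fraction) <= 1))
  if (sam_prevalence > 0 && missing_weight_rate >= 1 && oedema_fraction <= 0) {
    stop("infeasible spec: SAM cannot be generated with all weights missing ",
         "and no clinical signs", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Samples child records from a [cohort_spec()]: age band then integer age
#' within band, WAZ from the (SAM- or non-SAM-) normal model, weight
#' back-computed from the sampled WAZ through the growth reference (the
#' inverse of [compute_z()]), clinical SAM signs, TB/comorbidity/stage
#' flags, and finally the missingness mask.  Masking happens after
#' generation, so the unmasked truth is recoverable from
#' `attr(cohort, "truth")` for validation.  Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param reference A `growth_reference` table.
#' @return Tibble of child records (one row per child) with a `truth`
#'   attribute holding the pre-masking flags and sampled WAZ.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            reference = ncp_growth_reference()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(spec$seed)
  }
  n <- spec$n
  bands <- default_energy_tables()
  band_i <- sample.int(5, n, replace = TRUE, prob = spec$age_band_props)
  age <- bands$lo_months[band_i] +
    floor(stats::runif(n) * (bands$hi_months[band_i] - bands$lo_months[band_i] + 1))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sam <- stats::runif(n) < spec$sam_prevalence
  waz <- ifelse(sam,
                stats::rnorm(n, spec$sam_waz_mean, spec$sam_waz_sd),
                stats::rnorm(n, spec$waz_mean, spec$waz_sd))
  weight <- measurement_for_z("weight_for_age", sex, age, waz, reference)

  oedema_pick <- sam & stats::runif(n) < spec$oedema_fraction
  visible_wasting <- sam & !oedema_pick
  oedema <- oedema_pick

  tb <- stats::runif(n) < spec$tb_prevalence
  comorbidity <- !tb & stats::runif(n) < spec$comorbidity_prevalence
  stage <- ifelse(tb | comorbidity, 3L, sample(1:2, n, replace = TRUE))

  truth <- tibble::tibble(child_id = sprintf("S%04d", seq_len(n)),
                          waz = waz, prevalent_tb = tb,
                          comorbidity_increased_needs = comorbidity,
                          who_stage = stage, sam = sam)

  mask <- stats::runif(n) < spec$missing_morbidity_rate
  tb[mask] <- NA; comorbidity[mask] <- NA; stage[mask] <- NA
  weight[stats::runif(n) < spec$missing_weight_rate] <- NA
  muac <- rep(NA_real_, n)
  keep_muac <- stats::runif(n) >= spec$missing_muac_rate
  if (any(keep_muac)) {
    muac[keep_muac] <- round(115 + 0.35 * age[keep_muac] +
                               6 * waz[keep_muac] +
                               stats::rnorm(sum(keep_muac), 0, 5))
  }

  out <- tibble::tibble(
    child_id = truth$child_id,
    age_months = age, sex = sex,
    weight_kg = weight, height_cm = NA_real_, muac_mm = muac,
    visible_wasting = visible_wasting, bilateral_pedal_oedema = oedema,
    prevalent_tb = tb, comorbidity_increased_needs = comorbidity,
    who_stage = stage
  )
  attr(out, "truth") <- truth
  out
}

#' Deterministic fixture cohort reproducing the 2010 programme composition
#'
#' A hand-constructed cohort of 251 records that classifies to exactly 117
#' NCP-A, 88 NCP-B (40 via prevalent TB, 41 via moderate undernutrition, 7
#' via another comorbidity), 25 NCP-C (4 of whom also have TB) and 21
#' unassigned for missing morbidity data; with the NCP-B group's age-band
#' counts 9/12/19/21/27, the SAM group's 4/5/4/3/9, 92 children aged <= 3
#' years and 159 older, and 44 children with prevalent TB.  SAM weights are
#' chosen so that per-band stabilisation-phase calorie totals under the
#' half-supplementation rule match the published cohort costing (including
#' the 6.5 kg weight imputed for one infant whose weight was unrecorded);
#' all other weights are back-computed from target WAZ values through the
#' bundled growth reference.
#'
#' @param reference A `growth_reference` table used to invert WAZ targets
#'   into weights.
#' @return Tibble of 251 child records.
#' @export
fixture_cohort_2010 <- function(reference = ncp_growth_reference()) {
  rec <- function(age, z = NA, weight = NA, wasting = FALSE, oedema = FALSE,
                  tb = FALSE, com = FALSE, stage = NA) {
    tibble::tibble(age_months = age, z = z, weight_kg = weight,
                   visible_wasting = wasting, bilateral_pedal_oedema = oedema,
                   prevalent_tb = tb, comorbidity_increased_needs = com,
                   who_stage = stage)
  }

  # --- SAM group (25): band counts 4/5/4/3/9; weights solve the published
  # per-band stabilisation kcal totals (band weight sum = kcal / (rate*0.5*70));
  # 6-11-month ages chosen so the rehabilitation phase falls in the next band.
  sam_age <- c(10, 10, 11, 11,
               14, 16, 18, 20, 21,
               30, 40, 50, 60,
               80, 95, 110,
               125, 130, 140, 145, 150, 155, 160, 165, 170)
  sam_wt <- c(6.5, 4.9, 5.0, 5.5,
              7.6, 7.8, 8.0, 8.4, 8.6,
              9.5, 9.9, 10.2, 10.3,
              13.0, 13.6, 14.2,
              21.0, 21.8, 22.2, 22.6, 23.0, 23.4, 23.8, 24.4, 25.2)
  sam_tb <- c(rep(FALSE, 16), rep(TRUE, 4), rep(FALSE, 5))
  sam <- rec(sam_age, weight = sam_wt, wasting = TRUE,
             oedema = c(TRUE, TRUE, rep(FALSE, 23)), tb = sam_tb,
             stage = 4)

  # --- NCP-B group (88): band counts 9/12/19/21/27, split within band into
  # TB (4/5/9/10/12), moderate undernutrition (4/6/9/10/12) and other
  # comorbidity (1/1/1/1/3)
  b_ages <- list(
    c(6, 7, 8, 9, 10, 11, 6, 8, 10),
    12:23,
    c(24, 26, 28, 30, 32, 34, 35, 36, 38, 42, 46, 50, 54, 58, 62, 65, 68, 70, 71),
    seq(72, 112, by = 2),
    seq(120, 172, by = 2)
  )
  n_tb <- c(4, 5, 9, 10, 12); n_uw <- c(4, 6, 9, 10, 12); n_cm <- c(1, 1, 1, 1, 3)
  b_list <- list()
  uw_i <- 0; tb_i <- 0
  for (b in 1:5) {
    ages <- b_ages[[b]]
    role <- c(rep("tb", n_tb[b]), rep("uw", n_uw[b]), rep("cm", n_cm[b]))
    z <- ifelse(role == "uw",
                -2.05 - 0.02 * (uw_i + cumsum(role == "uw")),
                -0.8 - 0.02 * (tb_i + cumsum(role != "uw")))
    uw_i <- uw_i + n_uw[b]; tb_i <- tb_i + n_tb[b] + n_cm[b]
    b_list[[b]] <- rec(ages, z = z, tb = role == "tb", com = role == "cm",
                       stage = ifelse(role == "uw", 2, NA))
  }
  bgrp <- do.call(rbind, b_list)

  # --- unassigned (21): WAZ > -2 (or weight missing) with TB, comorbidity
  # and stage all unrecorded; SAM signs also unrecorded
  u_age <- c(8, 11, 13, 17, 22, 26, 33, 45, 58, 70,
             75, 90, 100, 115, 122, 135, 148, 152, 163, 171, 178)
  u <- rec(u_age, z = -1.5 + 0.05 * seq_along(u_age),
           wasting = NA, oedema = NA, tb = NA, com = NA)
  u$z[u_age == 100] <- NA  # one child with no weight recorded at all

  # --- NCP-A (117): adequately growing, no morbidity
  a_age <- c(c(6, 7, 8, 9, 10, 11, 6, 7, 8, 9),
             c(12:23, 12, 13),
             c(24:36, 24:32),
             seq(37, 65, by = 2),
             72:96,
             120:150)
  a <- rec(a_age, z = seq(-1.9, 1.0, length.out = length(a_age)),
           stage = rep(1:2, length.out = length(a_age)))

  cohort <- rbind(sam, bgrp, u, a)
  n <- nrow(cohort)
  cohort$child_id <- sprintf("C%03d", seq_len(n))
  cohort$sex <- rep(c("male", "female"), length.out = n)
  need_wt <- is.na(cohort$weight_kg) & !is.na(cohort$z)
  cohort$weight_kg[need_wt] <- measurement_for_z(
    "weight_for_age", cohort$sex[need_wt], cohort$age_months[need_wt],
    cohort$z[need_wt], reference)
  cohort$z <- NULL
  cohort$height_cm <- NA_real_
  cohort$muac_mm <- NA_real_
  cohort[, c("child_id", "age_months", "sex", "weight_kg", "height_cm",
             "muac_mm", "visible_wasting", "bilateral_pedal_oedema",
             "prevalent_tb", "comorbidity_increased_needs", "who_stage")]
}
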