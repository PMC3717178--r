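#' Define a supplement product
#'
#' @param name Product name.
#' @param unit_mass_g Mass of one supply unit in grams.
#' @param kcal_per_unit Energy content of one unit, kcal.
#' @param price_per_unit_zar Bulk purchase price of one unit, ZAR.
#' @return One-row tibble including the derived `cost_per_kcal_zar`.
#' @export
supplement_product <- function(name, unit_mass_g, kcal_per_unit,
                               price_per_unit_zar) {
  stopifnot(unit_mass_g > 0, kcal_per_unit > 0, price_per_unit_zar > 0)
  tibble::tibble(
    name = name, unit_mass_g = unit_mass_g, kcal_per_unit = kcal_per_unit,
    price_per_unit_zar = price_per_unit_zar,
    cost_per_kcal_zar = price_per_unit_zar / kcal_per_unit
  )
}

#' Default supplement products
#'
#' The two commercial products used in the costing: Sibusiso, a ready-to-use
#' food for the NCP-C stabilisation phase (0.021 ZAR/kcal), and Future Life
#' Porridge for NCP-B rehabilitation (0.009 ZAR/kcal), both supplied in
#' 500 g units at 2010 bulk prices.
#'
#' @return Tibble of products.
#' @export
default_products <- function() {
  rbind(
    supplement_product("Sibusiso", 500, 2650, 2650 * 0.021),
    supplement_product("Future Life Porridge", 500, 1880, 1880 * 0.009)
  )
}

#' 2010 mid-year ZAR/USD exchange rate
#'
#' @param usd_per_zar USD per ZAR; default 0.129 (02 July 2010).
#' @return Numeric scalar.
#' @export
exchange_rate <- function(usd_per_zar = 0.129) {
  stopifnot(usd_per_zar > 0)
  usd_per_zar
}

#' Feeding-course durations
#'
#' Default course structure: 26 weeks of NCP-B (182 days) for the
#' moderately undernourished group; for SAM, 10 weeks (70 days) of NCP-C
#' stabilisation followed by a rehabilitation phase on NCP-B for the
#' remainder of the half-year (182.5 - 70 = 112.5 days).  `band_advance`
#' moves the child's energy age band forward by the stabilisation-phase
#' length at the phase transition (70 days is ~2.3 months, so infants aged
#' 6-11 months at course start draw the 12-23-month NCP-B rate during
#' rehabilitation).
#'
#' @param ncp_b_days NCP-B-only course length, days (default 182).
#' @param sam_c_days SAM stabilisation phase, days (default 70).
#' @param sam_b_days SAM rehabilitation phase, days (default 112.5).
#' @param band_advance Advance the age band at the phase transition
#'   (default `TRUE`).
#' @return List of class `course_durations`.
#' @export
course_durations <- function(ncp_b_days = 182, sam_c_days = 70,
                             sam_b_days = 112.5, band_advance = TRUE) {
  stopifnot(ncp_b_days > 0, sam_c_days > 0, sam_b_days > 0)
  structure(list(ncp_b_days = ncp_b_days, sam_c_days = sam_c_days,
                 sam_b_days = sam_b_days, band_advance = band_advance),
            class = "course_durations")
}

#' Build the feeding course for a care plan
#'
#' NCP-B: a single porridge phase at the band's daily rate.  NCP-C: a
#' ready-to-use-food stabilisation phase at half the weight-based total
#' requirement, then a porridge rehabilitation phase at the NCP-B rate (age
#' band optionally advanced, see [course_durations()]).  NCP-A and
#' UNASSIGNED get an empty course (zero supplement cost) — plan A's extra
#' 10% of dietary energy is met from household food, not supplements.
#'
#' @param plan `"A"`, `"B"`, `"C"` or `"UNASSIGNED"`.
#' @param age_months Age at course start.
#' @param weight_kg Weight in kg; required for plan C.
#' @param policy An [energy_policy()].
#' @param products Product table as from [default_products()].
#' @param durations A [course_durations()].
#' @param tables Energy table.
#' @return Tibble of phases: `phase`, `plan`, `product`, `days`,
#'   `daily_kcal`, `kcal`.
#' @examples
#' course_for_plan("B", 36)  # 280 kcal/day x 182 d = 50,960 kcal
#' @export
course_for_plan <- function(plan, age_months, weight_kg = NA,
                            policy = energy_policy(),
                            products = default_products(),
                            durations = course_durations(),
                            tables = default_energy_tables()) {
  empty <- tibble::tibble(phase = integer(), plan = character(),
                          product = character(), days = numeric(),
                          daily_kcal = numeric(), kcal = numeric())
  if (plan %in% c("A", "UNASSIGNED")) return(empty)
  rtuf <- products$name[1]
  porridge <- products$name[nrow(products)]

  if (plan == "B") {
    daily <- ncp_b_daily_kcal(age_months, policy, tables)
    return(tibble::tibble(phase = 1L, plan = "B", product = porridge,
                          days = durations$ncp_b_days, daily_kcal = daily,
                          kcal = daily * durations$ncp_b_days))
  }
  if (plan == "C") {
    if (is.na(weight_kg)) {
      stop("plan C course requires a weight (impute one if unrecorded)",
           call. = FALSE)
    }
    daily_c <- ncp_c_daily_supplement_kcal(age_months, weight_kg, policy, tables)
    age2 <- if (durations$band_advance) {
      min(age_months + durations$sam_c_days / DAYS_PER_MONTH,
          max(tables$hi_months))
    } else {
      age_months
    }
    daily_b <- ncp_b_daily_kcal(age2, policy, tables)
    return(tibble::tibble(
      phase = 1:2, plan = c("C", "B"), product = c(rtuf, porridge),
      days = c(durations$sam_c_days, durations$sam_b_days),
      daily_kcal = c(daily_c, daily_b),
      kcal = c(daily_c * durations$sam_c_days, daily_b * durations$sam_b_days)
    ))
  }
  stop("unknown plan: ", plan, call. = FALSE)
}

product_cost_per_kcal <- function(products, name) {
  i <- match(name, products$name)
  if (any(is.na(i))) {
    stop("unknown product(s): ", paste(unique(name[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  products$cost_per_kcal_zar[i]
}

#' Cost a feeding course
#'
#' One cost line per phase: total kcal times the product's ZAR/kcal, rounded
#' half-away-from-zero to whole ZAR per line, with the USD value at the
#' given exchange rate.
#'
#' @param course Tibble of phases from [course_for_plan()].
#' @param products Product table.
#' @param fx USD per ZAR.
#' @return Tibble of cost lines (`phase`, `product`, `kcal`, `cost_zar`,
#'   `cost_usd`).
#' @export
cost_course <- function(course, products = default_products(),
                        fx = exchange_rate()) {
  cpk <- product_cost_per_kcal(products, course$product)
  cost_zar <- round_half_away(course$kcal * cpk)
  tibble::tibble(phase = course$phase, product = course$product,
                 kcal = course$kcal, cost_zar = cost_zar,
                 cost_usd = cost_zar * fx)
}

#' Cohort supplement cost summary
#'
#' Costs every supplementation course in a classified cohort, aggregated the
#' way the published tables are: the NCP-B-only group is costed per child
#' (all children in a band share one weight-independent course) and summed
#' by band; the SAM group's weight-dependent calories are summed per band
#' and each band row is rounded to whole ZAR per product phase.  Per-child
#' means are totals divided by group size, rounded to whole ZAR.
#'
#' @param classification An `ncp_classification` from [classify_cohort()].
#' @param records The cohort records (weights are needed for SAM costing; a
#'   SAM child without a weight stops with an error — impute before costing).
#' @param policy,products,fx,durations,tables See the respective helpers.
#' @return Object of class `cohort_cost_summary`: list with tibbles `ncp_b`
#'   (band, daily_kcal, kcal_per_child, cost_per_child_zar, n, cost_zar),
#'   `sam` (band, n, kcal_c, cost_c_zar, kcal_b, cost_b_zar, cost_zar),
#'   `child_costs` (per-child rounded course costs with TB flag), and
#'   `totals` (ZAR/USD totals and per-child means).
#' @export
cohort_cost_table <- function(classification, records,
                              policy = energy_policy(),
                              products = default_products(),
                              fx = exchange_rate(),
                              durations = course_durations(),
                              tables = default_energy_tables()) {
  records <- complete_record_columns(records)
  asg <- classification$assignments
  stopifnot(identical(asg$child_id, records$child_id))
  porridge_cpk <- product_cost_per_kcal(products, products$name[nrow(products)])
  rtuf_cpk <- product_cost_per_kcal(products, products$name[1])

  # --- NCP-B-only group: per-child course, rounded per child, counted by band
  b_idx <- which(asg$plan == "B")
  b_band_i <- band_index(asg$age_months[b_idx], tables)
  daily <- if (policy$bound == "upper") tables$b_upper else tables$b_lower
  kcal_per_child <- daily * durations$ncp_b_days
  cost_per_child <- round_half_away(kcal_per_child * porridge_cpk)
  n_b_band <- tabulate(b_band_i, nbins = nrow(tables))
  ncp_b <- tibble::tibble(
    band = tables$band,
    daily_kcal = daily,
    kcal_per_child = kcal_per_child,
    cost_per_child_zar = cost_per_child,
    n = n_b_band,
    cost_zar = cost_per_child * n_b_band
  )
  b_total <- sum(ncp_b$cost_zar)

  # --- SAM group: per-child weight-based phase kcal, summed and rounded by band
  c_idx <- which(asg$plan == "C")
  sam_children <- lapply(c_idx, function(i) {
    crs <- course_for_plan("C", records$age_months[i], records$weight_kg[i],
                           policy, products, durations, tables)
    tibble::tibble(band_i = band_index(asg$age_months[i], tables),
                   kcal_c = crs$kcal[1], kcal_b = crs$kcal[2],
                   cost_zar = sum(cost_course(crs, products, fx)$cost_zar))
  })
  sam_df <- if (length(sam_children) > 0) do.call(rbind, sam_children) else
    tibble::tibble(band_i = integer(), kcal_c = numeric(), kcal_b = numeric(),
                   cost_zar = numeric())
  agg <- function(v) vapply(seq_len(nrow(tables)),
                            function(b) sum(v[sam_df$band_i == b]), numeric(1))
  kcal_c <- agg(sam_df$kcal_c); kcal_b <- agg(sam_df$kcal_b)
  cost_c <- round_half_away(kcal_c * rtuf_cpk)
  cost_b <- round_half_away(kcal_b * porridge_cpk)
  sam <- tibble::tibble(
    band = tables$band,
    n = tabulate(sam_df$band_i, nbins = nrow(tables)),
    kcal_c = kcal_c, cost_c_zar = cost_c,
    kcal_b = kcal_b, cost_b_zar = cost_b,
    cost_zar = cost_c + cost_b
  )
  sam_total <- sum(sam$cost_zar)

  # per-child cost lines (used for stratified scenario re-costing)
  child_costs <- tibble::tibble(
    child_id = c(asg$child_id[b_idx], asg$child_id[c_idx]),
    plan = c(rep("B", length(b_idx)), rep("C", length(c_idx))),
    prevalent_tb = c(records$prevalent_tb[b_idx], records$prevalent_tb[c_idx]),
    cost_zar = c(cost_per_child[b_band_i], sam_df$cost_zar)
  )

  supplement_zar <- b_total + sam_total
  totals <- list(
    ncp_b_zar = b_total,
    ncp_b_usd = round_half_away(b_total * fx),
    ncp_b_per_child_zar = if (length(b_idx) > 0)
      round_half_away(b_total / length(b_idx)) else 0,
    sam_zar = sam_total,
    sam_usd = round_half_away(sam_total * fx),
    sam_per_child_zar = if (length(c_idx) > 0)
      round_half_away(sam_total / length(c_idx)) else 0,
    sam_c_zar = sum(cost_c),
    sam_b_zar = sum(cost_b),
    supplement_zar = supplement_zar,
    supplement_usd = round_half_away(supplement_zar * fx)
  )
  structure(list(ncp_b = ncp_b, sam = sam, child_costs = child_costs,
                 totals = totals, fx = fx, policy = policy,
                 durations = durations),
            class = "cohort_cost_summary")
}

#' @export
print.cohort_cost_summary <- function(x, ...) {
  cat("Supplement costs (", x$policy$bound, "-bound energy policy)\n", sep = "")
  cat("NCP-B-only group:\n"); print(as.data.frame(x$ncp_b))
  cat("SAM group:\n"); print(as.data.frame(x$sam))
  cat(sprintf("Totals: NCP-B ZAR%s, SAM ZAR%s, combined ZAR%s ($%s)\n",
              format(x$totals$ncp_b_zar, big.mark = ","),
              format(x$totals$sam_zar, big.mark = ","),
              format(x$totals$supplement_zar, big.mark = ","),
              format(x$totals$supplement_usd, big.mark = ",")))
  invisible(x)
}
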