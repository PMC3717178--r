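#' Default pipeline configuration
#'
#' All tunables of the costing pipeline in one list: supplement products and
#' exchange rate, energy tables and policy bound, course durations, ART
#' regimen costs, classifier options, the printed upper-limit increment for
#' unassigned children, and the bundled sensitivity scenarios.
#'
#' @return Nested list.
#' @export
default_config <- function() {
  list(
    products = default_products(),
    usd_per_zar = 0.129,
    energy_tables = default_energy_tables(),
    policy = list(bound = "upper", ncp_c_supplement_fraction = 0.5),
    durations = list(ncp_b_days = 182, sam_c_days = 70, sam_b_days = 112.5,
                     band_advance = TRUE),
    regimens = art_regimens(),
    classifier = list(inclusive_moderate = TRUE, stage_trigger = TRUE),
    # Cost of treating all unassigned children as NCP-B for the upper-limit
    # estimate: "printed" uses upper_limit_increment_zar as published;
    # "derive" recomputes it from the unassigned children's ages.
    upper_limit_mode = "printed",
    upper_limit_increment_zar = 12449,
    scenarios = list(
      scenario_spec("12-week NCP-B, 10+6-week SAM", ncp_b_weeks = 12,
                    sam_c_weeks = 10, sam_b_weeks = 6),
      scenario_spec("26-week NCP-B, 6-week NCP-C + 20-week NCP-B SAM",
                    ncp_b_weeks = 26, sam_c_weeks = 6, sam_b_weeks = 20)
    )
  )
}

#' Load a pipeline configuration file
#'
#' Reads a YAML or JSON config and merges it over [default_config()]
#' (scalars and nested fields override; anything unspecified keeps its
#' default).  `products` and `energy_tables` given as lists of records are
#' converted to tibbles; scenario blocks become [scenario_spec()]s.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Config list.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(default_config(), raw)
  if (!is.null(raw$products)) {
    pr <- tibble::as_tibble(raw$products)
    cfg$products <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
      supplement_product(pr$name[i], pr$unit_mass_g[i], pr$kcal_per_unit[i],
                         pr$price_per_unit_zar[i])
    }))
  }
  if (!is.null(raw$energy_tables)) {
    cfg$energy_tables <- tibble::as_tibble(raw$energy_tables)
  }
  if (!is.null(raw$scenarios)) {
    cfg$scenarios <- lapply(raw$scenarios, function(s) do.call(scenario_spec, s))
  }
  cfg
}

#' Read a cohort CSV
#'
#' One row per child with columns named as in the child-record schema; empty
#' cells are missing values.  Schema violations are reported with row
#' numbers.
#'
#' @param path CSV path.
#' @return Cohort tibble.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("child_id", "age_months", "sex")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    stop("cohort CSV lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("visible_wasting", "bilateral_pedal_oedema", "prevalent_tb",
                "comorbidity_increased_needs")) {
    if (!is.null(df[[col]])) df[[col]] <- as.logical(df[[col]])
  }
  records <- complete_record_columns(df)
  validate_cohort(records)
  records
}

#' Write a cohort to CSV
#'
#' @param records Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  drop <- vapply(records, is.list, logical(1))
  utils::write.csv(records[!drop], path, row.names = FALSE, na = "")
  invisible(path)
}

upper_limit_increment <- function(classification, config) {
  if (identical(config$upper_limit_mode, "derive")) {
    asg <- classification$assignments
    ages <- asg$age_months[asg$plan == "UNASSIGNED"]
    porridge_cpk <- config$products$cost_per_kcal_zar[nrow(config$products)]
    policy <- do.call(energy_policy, config$policy)
    kcal <- ncp_b_daily_kcal(ages, policy, config$energy_tables) *
      config$durations$ncp_b_days
    sum(round_half_away(kcal * porridge_cpk))
  } else {
    config$upper_limit_increment_zar
  }
}

#' Run the full costing pipeline
#'
#' Classify -> energy -> supplement cost -> ART comparison -> proportional
#' costs -> upper-limit estimate -> sensitivity scenarios, end-to-end
#' deterministic for fixed inputs.  Children who cannot be classified are
#' carried as UNASSIGNED (never dropped) and enter the upper-limit estimate.
#'
#' @param cohort Cohort tibble or path to a cohort CSV.
#' @param config Config list as from [default_config()] / [load_config()].
#' @param reference A `growth_reference` table.
#' @param output_dir If non-`NULL`, writes report CSVs (cost tables by
#'   NCP-B/SAM group, ART table), a JSON summary and a run log there.
#' @return Object of class `ncp_pipeline_summary`: `classification`,
#'   `costs`, `art`, `proportional` (26/52-week percentages),
#'   `upper_limit` (ZAR/USD), `scenarios` (list of scenario results),
#'   `eligible_pct`.
#' @examples
#' \donttest{
#' res <- run_pipeline(fixture_cohort_2010())
#' res$costs$totals$supplement_zar
#' }
#' @export
run_pipeline <- function(cohort, config = default_config(),
                         reference = ncp_growth_reference(),
                         output_dir = NULL) {
  records <- if (is.character(cohort)) read_cohort(cohort) else
    complete_record_columns(cohort)

  if (nrow(records) == 0) {
    return(structure(list(classification = NULL, costs = NULL, art = NULL,
                          proportional = c(`26wk` = NA, `52wk` = NA),
                          upper_limit = list(zar = 0, usd = 0),
                          scenarios = list(), eligible_pct = NA),
                     class = "ncp_pipeline_summary"))
  }

  policy <- do.call(energy_policy, config$policy)
  durations <- do.call(course_durations, config$durations)
  fx <- exchange_rate(config$usd_per_zar)

  cl <- classify_cohort(records, reference,
                        inclusive_moderate = config$classifier$inclusive_moderate,
                        stage_trigger = config$classifier$stage_trigger)
  costs <- cohort_cost_table(cl, records, policy, config$products, fx,
                             durations, config$energy_tables)

  n_young <- sum(records$age_months <= 36, na.rm = TRUE)
  n_old <- sum(records$age_months > 36, na.rm = TRUE)
  art <- cohort_art_cost(n_young, n_old, config$regimens, fx)

  supp <- costs$totals$supplement_zar
  proportional <- c(
    `26wk` = proportional_cost(supp, art$total_zar, 26),
    `52wk` = proportional_cost(supp, art$total_zar, 52)
  )
  increment <- upper_limit_increment(cl, config)
  upper_limit <- list(
    increment_zar = increment,
    zar = supp + increment,
    usd = round_half_away((supp + increment) * fx)
  )

  base <- scenario_base(costs, art$total_zar, fx)
  scen <- lapply(config$scenarios %||% list(), run_scenario, base = base)

  out <- structure(list(
    classification = cl, costs = costs, art = art,
    proportional = proportional, upper_limit = upper_limit,
    scenarios = scen, eligible_pct = cl$eligible_pct, config = config
  ), class = "ncp_pipeline_summary")

  if (!is.null(output_dir)) write_reports(out, output_dir)
  out
}

write_reports <- function(summary, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary$costs$ncp_b,
                   file.path(output_dir, "ncp_b_costs.csv"), row.names = FALSE)
  utils::write.csv(summary$costs$sam,
                   file.path(output_dir, "sam_costs.csv"), row.names = FALSE)
  art_tab <- summary$art$by_group
  utils::write.csv(art_tab, file.path(output_dir, "art_costs.csv"),
                   row.names = FALSE)
  js <- list(
    counts = as.list(summary$classification$counts),
    eligible_pct = summary$eligible_pct,
    supplement_zar = summary$costs$totals$supplement_zar,
    supplement_usd = summary$costs$totals$supplement_usd,
    art_zar = summary$art$total_zar,
    art_usd = summary$art$total_usd,
    proportional_pct = as.list(summary$proportional),
    upper_limit = summary$upper_limit,
    scenarios = lapply(summary$scenarios, function(s) s[c(
      "name", "total_zar", "total_usd", "pct_26wk", "pct_52wk")])
  )
  jsonlite::write_json(js, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    paste0("ncpcost run: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("n = ", summary$classification$n),
    paste0("config_hash = ",
           sum(utf8ToInt(jsonlite::toJSON(summary$config$policy,
                                          auto_unbox = TRUE))))
  )
  writeLines(log_lines, file.path(output_dir, "run.log"))
  invisible(output_dir)
}

#' @export
print.ncp_pipeline_summary <- function(x, ...) {
  if (is.null(x$classification)) {
    cat("Empty cohort: zero-cost summary\n")
    return(invisible(x))
  }
  print(x$classification)
  cat(sprintf("Supplements: ZAR%s ($%s); ART 26 wk: ZAR%s ($%s)\n",
              format(x$costs$totals$supplement_zar, big.mark = ","),
              format(x$costs$totals$supplement_usd, big.mark = ","),
              format(x$art$total_zar, big.mark = ","),
              format(x$art$total_usd, big.mark = ",")))
  cat(sprintf("Proportional cost: %s%% (26 wk), %s%% (52 wk); upper limit ZAR%s ($%s)\n",
              x$proportional[["26wk"]], x$proportional[["52wk"]],
              format(x$upper_limit$zar, big.mark = ","),
              format(x$upper_limit$usd, big.mark = ",")))
  for (s in x$scenarios) print(s)
  invisible(x)
}
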