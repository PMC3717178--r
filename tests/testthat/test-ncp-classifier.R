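ref <- ncp_growth_reference()

assign1 <- function(rec, ...) {
  a <- assess_child(rec, ref)
  assign_ncp(a, rec, ...)
}

test_that("single-child assignments follow the care-plan rules", {
  w_uw <- measurement_for_z("weight_for_age", "male", 30, -2.5, ref)
  asg <- assign1(child(30, weight = w_uw, wasting = FALSE, oedema = FALSE,
                       tb = FALSE, com = FALSE, stage = 2))
  expect_equal(asg$plan, "B")
  expect_equal(asg$reasons, "UNDERWEIGHT")

  w_ok <- measurement_for_z("weight_for_age", "male", 30, -1.2, ref)
  asg <- assign1(child(30, weight = w_ok, tb = TRUE))
  expect_equal(asg$plan, "B")
  expect_equal(asg$reasons, "TB")

  # WAZ > -2 and no morbidity data at all -> unassigned
  asg <- assign1(child(30, weight = w_ok))
  expect_equal(asg$plan, "UNASSIGNED")
  expect_equal(asg$reasons, "MISSING_DATA")

  # stage 3/4 is a trigger, configurable off
  rec <- child(30, weight = w_ok, tb = FALSE, com = FALSE, stage = 3)
  expect_equal(assign1(rec)$plan, "B")
  expect_equal(assign1(rec, stage_trigger = FALSE)$plan, "A")

  # SAM with TB goes to C, not B
  asg <- assign1(child(30, weight = w_ok, wasting = TRUE, tb = TRUE))
  expect_equal(asg$plan, "C")
  expect_equal(asg$reasons, "SAM_WASTING")
})

test_that("a positive trigger beats missingness elsewhere", {
  w_uw <- measurement_for_z("weight_for_age", "male", 30, -2.5, ref)
  asg <- assign1(child(30, weight = w_uw))  # everything else missing
  expect_equal(asg$plan, "B")
  expect_equal(asg$reasons, "UNDERWEIGHT")
})

test_that("adding a SAM sign never yields plan B; removing B-triggers never keeps B", {
  set.seed(23)
  for (i in 1:100) {
    rec <- child(sample(6:179, 1),
                 weight = runif(1, 4, 40),
                 tb = sample(c(TRUE, FALSE, NA), 1),
                 com = sample(c(TRUE, FALSE, NA), 1),
                 stage = sample(c(1:4, NA), 1))
    with_sign <- rec; with_sign$bilateral_pedal_oedema <- TRUE
    expect_equal(assign1(with_sign)$plan, "C")

    stripped <- rec
    stripped$prevalent_tb <- FALSE
    stripped$comorbidity_increased_needs <- FALSE
    stripped$who_stage <- 1
    stripped$weight_kg <- measurement_for_z("weight_for_age", "male",
                                            stripped$age_months, -1, ref)
    stripped$visible_wasting <- FALSE
    stripped$bilateral_pedal_oedema <- FALSE
    expect_true(assign1(stripped)$plan %in% c("A"))
  }
})

test_that("classify_cohort partitions the cohort and tallies by band", {
  cohort <- fixture_cohort_2010()
  cl <- classify_cohort(cohort)
  expect_equal(sum(cl$counts), nrow(cohort))
  expect_equal(cl$eligible, unname(cl$counts[["B"]] + cl$counts[["C"]]))
  expect_equal(unname(cl$band_counts["B", ]), c(9, 12, 19, 21, 27))
  expect_equal(unname(cl$band_counts["C", ]), c(4, 5, 4, 3, 9))

  well <- child(30, weight = measurement_for_z("weight_for_age", "male", 30, -0.5, ref),
                wasting = FALSE, oedema = FALSE, tb = FALSE, com = FALSE,
                stage = 1)
  allA <- do.call(rbind, lapply(1:5, function(i) {
    w <- well; w$child_id <- paste0("K", i); w
  }))
  expect_equal(unname(classify_cohort(allA)$counts[["A"]]), 5)

  dup <- rbind(well, well)
  expect_error(classify_cohort(dup), "duplicate child_id")
})

test_that("weight-history flags feed the classifier as B-triggers", {
  w_ok <- measurement_for_z("weight_for_age", "male", 30, -1, ref)
  rec <- child(30, weight = w_ok, tb = FALSE, com = FALSE, stage = 1)
  rec$visit_weights <- list(tibble::tibble(
    date = as.Date(c("2010-01-01", "2010-02-01")),
    weight_kg = c(10.0, 9.4)))
  cl <- classify_cohort(rec)
  expect_equal(cl$assignments$plan, "B")
  expect_equal(cl$assignments$reasons[[1]], "WEIGHT_LOSS")
})
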