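test_that("the fixture cohort reproduces every published count", {
  rec <- fixture_cohort_2010()
  expect_equal(nrow(rec), 251)
  cl <- classify_cohort(rec)
  expect_equal(as.vector(cl$counts), c(117, 88, 25, 21))
  expect_equal(as.vector(cl$reason_counts[c("TB", "UNDERWEIGHT", "COMORBIDITY")]),
               c(40, 41, 7))
  expect_equal(sum(rec$prevalent_tb, na.rm = TRUE), 44)
  expect_equal(sum(rec$age_months <= 36), 92)
  expect_equal(sum(rec$age_months > 36), 159)
  # SAM age-band counts 4/5/4/3/9, incl. the 6.5 kg imputed infant
  sam <- rec[cl$assignments$plan == "C", ]
  expect_equal(as.vector(table(age_band(sam$age_months))[
    c("6-11 months", "12-23 months", "2-5 years", "6-9 years", "10-14 years")]),
    c(4, 5, 4, 3, 9))
  expect_true(6.5 %in% sam$weight_kg)
})

test_that("fixture SAM weights reproduce the published stabilisation kcal totals", {
  rec <- fixture_cohort_2010()
  cl <- classify_cohort(rec)
  sam <- rec[cl$assignments$plan == "C", ]
  kcal <- vapply(seq_len(nrow(sam)), function(i) {
    course_for_plan("C", sam$age_months[i], sam$weight_kg[i])$kcal[1]
  }, numeric(1))
  by_band <- tapply(kcal, band_index_of <- findInterval(
    sam$age_months, c(6, 12, 24, 72, 120)), sum)
  expect_equal(as.vector(by_band), c(168630, 311080, 307230, 142800, 653310),
               tolerance = 1e-9)
})

test_that("generation is deterministic given a seed", {
  sp <- cohort_spec(seed = 99)
  expect_identical(generate_cohort(sp), generate_cohort(sp))
  sp2 <- cohort_spec(seed = 100)
  expect_false(identical(generate_cohort(sp), generate_cohort(sp2)))
})

test_that("zero SAM prevalence yields zero NCP-C", {
  sp <- cohort_spec(n = 120, seed = 3, sam_prevalence = 0)
  cl <- classify_cohort(generate_cohort(sp))
  expect_equal(unname(cl$counts[["C"]]), 0)
})

test_that("weights round-trip through the growth reference", {
  sp <- cohort_spec(n = 150, seed = 12)
  g <- generate_cohort(sp)
  truth <- attr(g, "truth")
  waz <- compute_z("weight_for_age", g$sex, g$age_months, g$weight_kg)
  expect_equal(waz, truth$waz, tolerance = 1e-6)
})

test_that("masking hides but does not alter the generated truth", {
  sp <- cohort_spec(n = 400, seed = 8, missing_morbidity_rate = 0.3)
  g <- generate_cohort(sp)
  truth <- attr(g, "truth")
  masked <- is.na(g$prevalent_tb)
  expect_gt(sum(masked), 0)
  expect_equal(g$prevalent_tb[!masked], truth$prevalent_tb[!masked])
  expect_true(all(is.na(g$who_stage[masked])))
})

test_that("infeasible specs are rejected", {
  expect_error(cohort_spec(sam_prevalence = 0.1, missing_weight_rate = 1,
                           oedema_fraction = 0), "infeasible")
  expect_error(cohort_spec(n = 0))
  expect_error(cohort_spec(age_band_props = c(1, 1, 1, 1, 1)))
})
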