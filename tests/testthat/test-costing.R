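test_that("rounding is half-away-from-zero and float-safe", {
  expect_equal(round_half_away(769.5), 770)
  expect_equal(round_half_away(85500 * 0.009), 770)   # binary artifact guard
  expect_equal(round_half_away(1154.25), 1154)
  expect_equal(round_half_away(-769.5), -770)
  expect_equal(round_half_away(11.577, 1), 11.6)
})

test_that("products derive cost per kcal; defaults price the two supplements", {
  p <- default_products()
  expect_equal(p$cost_per_kcal_zar, c(0.021, 0.009), tolerance = 1e-12)
  expect_equal(p$cost_per_kcal_zar, p$price_per_unit_zar / p$kcal_per_unit)
  expect_error(supplement_product("x", 500, -1, 10), ">")
})

test_that("course_for_plan builds the published course structures", {
  b <- course_for_plan("B", 36)
  expect_equal(nrow(b), 1)
  expect_equal(b$kcal, 280 * 182)  # 50,960

  cc <- course_for_plan("C", 18, weight_kg = 10)
  expect_equal(cc$plan, c("C", "B"))
  expect_equal(cc$kcal[1], 1100 * 70)
  expect_equal(cc$kcal[2], 190 * 112.5)  # 21,375: rehabilitation at band rate

  # band advance pushes a 10-month-old into the 12-23-month rate for phase 2
  infant <- course_for_plan("C", 10, weight_kg = 6.5)
  expect_equal(infant$daily_kcal[2], 190)
  frozen <- course_for_plan("C", 10, weight_kg = 6.5,
                            durations = course_durations(band_advance = FALSE))
  expect_equal(frozen$daily_kcal[2], 150)

  expect_equal(nrow(course_for_plan("A", 30)), 0)
  expect_equal(nrow(course_for_plan("UNASSIGNED", 30)), 0)
  expect_error(course_for_plan("C", 18), "weight")
})

test_that("cost_course rounds per line to whole ZAR", {
  b <- course_for_plan("B", 36)
  cl <- cost_course(b)
  expect_equal(cl$cost_zar, 459)  # 50,960 x 0.009 = 458.64
  expect_equal(cl$cost_usd, 459 * 0.129)

  zero <- cost_course(course_for_plan("A", 30))
  expect_equal(sum(zero$cost_zar), 0)

  bad <- b; bad$product <- "nope"
  expect_error(cost_course(bad), "unknown product")
})

fixture_summary <- function(...) {
  rec <- fixture_cohort_2010()
  cohort_cost_table(classify_cohort(rec), rec, ...)
}

test_that("the fixture cohort reproduces both published cost tables", {
  cc <- fixture_summary()
  expect_equal(cc$ncp_b$cost_per_child_zar, c(246, 311, 459, 622, 655))
  expect_equal(cc$ncp_b$cost_zar, c(2214, 3732, 8721, 13062, 17685))
  expect_equal(cc$totals$ncp_b_zar, 45414)
  expect_equal(cc$totals$ncp_b_per_child_zar, 516)

  expect_equal(cc$sam$kcal_c, c(168630, 311080, 307230, 142800, 653310))
  expect_equal(cc$sam$cost_c_zar, c(3541, 6533, 6452, 2999, 13720))
  expect_equal(cc$sam$kcal_b, c(85500, 106875, 126000, 128250, 405000))
  expect_equal(cc$sam$cost_b_zar, c(770, 962, 1134, 1154, 3645))
  expect_equal(cc$totals$sam_zar, 40910)
  expect_equal(cc$totals$sam_per_child_zar, 1636)
  expect_equal(cc$totals$supplement_zar, 86324)
  expect_equal(cc$totals$supplement_usd, 11136)
})

test_that("band costs conserve to group totals", {
  cc <- fixture_summary()
  expect_equal(sum(cc$ncp_b$cost_zar), cc$totals$ncp_b_zar)
  expect_equal(sum(cc$sam$cost_zar), cc$totals$sam_zar)
  expect_equal(sum(cc$sam$cost_c_zar), cc$totals$sam_c_zar)
  expect_equal(sum(cc$sam$cost_b_zar), cc$totals$sam_b_zar)
})

test_that("doubling the exchange rate doubles USD and leaves ZAR unchanged", {
  cc1 <- fixture_summary()
  cc2 <- fixture_summary(fx = exchange_rate(0.258))
  expect_equal(cc2$totals$supplement_zar, cc1$totals$supplement_zar)
  expect_equal(cc2$totals$supplement_usd, 2 * cc1$totals$supplement_usd)
})

test_that("lower-bound energy policy never costs more than the upper bound", {
  up <- fixture_summary()
  lo <- fixture_summary(policy = energy_policy("lower"))
  expect_true(all(lo$ncp_b$cost_zar <= up$ncp_b$cost_zar))
  expect_true(all(lo$sam$cost_zar <= up$sam$cost_zar))
  expect_lte(lo$totals$supplement_zar, up$totals$supplement_zar)
})

test_that("cost is monotone non-decreasing in course duration", {
  set.seed(31)
  for (i in 1:20) {
    age <- sample(6:170, 1); w <- runif(1, 4, 35)
    d1 <- sample(30:180, 1); d2 <- d1 + sample(1:60, 1)
    c1 <- sum(cost_course(course_for_plan(
      "C", age, w, durations = course_durations(sam_c_days = d1)))$cost_zar)
    c2 <- sum(cost_course(course_for_plan(
      "C", age, w, durations = course_durations(sam_c_days = d2)))$cost_zar)
    expect_lte(c1, c2)
  }
})
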