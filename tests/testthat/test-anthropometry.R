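test_that("MUAC cutoffs are age-banded and strictly less-than", {
  expect_true(muac_below_cutoff(24, 110))
  expect_false(muac_below_cutoff(24, 115))   # boundary equals not-SAM
  expect_true(muac_below_cutoff(150, 159))   # 10-14 y cutoff is 160 mm
  expect_false(muac_below_cutoff(150, 160))
  expect_true(muac_below_cutoff(70, 128))    # 5-9 y band
  expect_false(muac_below_cutoff(60, 116))   # still in the 115 mm band
  expect_error(muac_below_cutoff(4, 120), "\\[6, 179\\]")
  expect_error(muac_below_cutoff(24, 0), "> 0")
})

test_that("weight history gives loss / flattening / not-evaluable", {
  d <- as.Date(c("2010-01-01", "2010-02-01"))
  h <- assess_weight_history(data.frame(date = d, weight_kg = c(10.0, 9.4)))
  expect_true(h$confirmed_weight_loss)   # 6% > 5%
  expect_false(h$growth_curve_flattening)

  h <- assess_weight_history(data.frame(date = d, weight_kg = c(10.0, 10.0)))
  expect_false(h$confirmed_weight_loss)
  expect_true(h$growth_curve_flattening) # zero gain

  h <- assess_weight_history(data.frame(date = d[1], weight_kg = 10.0))
  expect_true(is.na(h$confirmed_weight_loss))
  expect_true(is.na(h$growth_curve_flattening))

  expect_error(
    assess_weight_history(data.frame(date = rev(d), weight_kg = c(10, 9))),
    "chronological")
})

test_that("assess_child applies SAM and moderate-undernutrition definitions", {
  ref <- ncp_growth_reference()
  # weight-only record at WAZ -2.5: moderate, not SAM
  w <- measurement_for_z("weight_for_age", "male", 30, -2.5, ref)
  a <- assess_child(child(30, weight = w, wasting = FALSE, oedema = FALSE), ref)
  expect_false(a$sam)
  expect_true(a$moderate_undernutrition)
  expect_equal(a$waz, -2.5, tolerance = 1e-9)

  # bilateral pedal oedema trumps a reassuring WAZ
  w1 <- measurement_for_z("weight_for_age", "male", 30, -1, ref)
  a <- assess_child(child(30, weight = w1, oedema = TRUE), ref)
  expect_true(a$sam)
  expect_false(a$moderate_undernutrition)

  # well-nourished
  w2 <- measurement_for_z("weight_for_age", "male", 30, -0.5, ref)
  a <- assess_child(child(30, weight = w2, wasting = FALSE, oedema = FALSE), ref)
  expect_false(a$sam)
  expect_false(a$moderate_undernutrition)
})

test_that("the moderate threshold is inclusive by default, strict on request", {
  # L = 1, M = 12, S = 0.25 puts 6 kg at exactly z = -2 in double arithmetic
  ref2 <- make_ref(L = 1, M = 12, S = 0.25, idx = c(40, 60))
  expect_true(assess_child(child(48, weight = 6),
                           ref2)$moderate_undernutrition)
  expect_false(assess_child(child(48, weight = 6), ref2,
                            inclusive_moderate = FALSE)$moderate_undernutrition)
})

test_that("missing measurements are reported missing, never defaulted", {
  ref <- ncp_growth_reference()
  w <- measurement_for_z("weight_for_age", "male", 30, -2.5, ref)
  full <- assess_child(child(30, weight = w, muac = 130), ref)
  expect_false(is.na(full$muac_below_cutoff))

  dropped <- assess_child(child(30, weight = w), ref)
  expect_true(is.na(dropped$muac_below_cutoff))  # moved to missing, not FALSE
  expect_true(all(c("muac_mm", "height_cm") %in% dropped$missing_fields))

  no_weight <- assess_child(child(30), ref)
  expect_true(is.na(no_weight$waz))
  expect_true(is.na(no_weight$moderate_undernutrition))
  expect_false(no_weight$sam)  # absence of signs is data, not SAM
})

test_that("SAM and moderate undernutrition are never both true", {
  ref <- ncp_growth_reference()
  set.seed(11)
  for (i in 1:50) {
    age <- sample(6:179, 1)
    z <- rnorm(1, -2, 1.5)
    w <- measurement_for_z("weight_for_age", "male", age, z, ref)
    a <- assess_child(child(age, weight = w,
                            wasting = sample(c(TRUE, FALSE, NA), 1),
                            oedema = sample(c(TRUE, FALSE, NA), 1)), ref)
    expect_false(isTRUE(a$sam) && isTRUE(a$moderate_undernutrition))
  }
})
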