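test_that("z is zero at the median and reduces to (X-M)/(M*S) when L = 1", {
  ref <- make_ref(L = -0.2, M = 9.0, S = 0.11)
  expect_equal(compute_z("weight_for_age", "male", 10, 9.0, ref), 0)

  ref1 <- make_ref(L = 1, M = 10, S = 0.1)
  x <- c(9, 10, 10.5, 11.2)
  expect_equal(compute_z("weight_for_age", "male", 10, x, ref1),
               (x - 10) / (10 * 0.1))
})

test_that("z-scores match an independently coded LMS oracle", {
  ref <- make_ref(L = -0.35, M = 9.0, S = 0.11)
  z <- compute_z("weight_for_age", "male", 10, 7.0, ref)
  expect_equal(z, lms_oracle(7.0, -0.35, 9.0, 0.11), tolerance = 1e-12)
  expect_equal(z, -2.38816877566459, tolerance = 1e-9)

  # tail-adjusted cases on both sides
  for (x in c(4.0, 4.8, 16.0, 20.0)) {
    expect_equal(compute_z("weight_for_age", "male", 10, x, ref),
                 lms_oracle(x, -0.35, 9.0, 0.11), tolerance = 1e-12)
  }
})

test_that("parameters are linearly interpolated between bracketing rows", {
  ref <- as_growth_reference(data.frame(
    indicator = "weight_for_age", sex = "male", index = c(10, 12),
    L = c(-0.2, -0.4), M = c(9, 10), S = c(0.10, 0.12)))
  z <- compute_z("weight_for_age", "male", 11, 9.5, ref)
  expect_equal(z, lms_oracle(9.5, -0.3, 9.5, 0.11), tolerance = 1e-12)
})

test_that("z is strictly increasing in the measurement", {
  ref <- ncp_growth_reference()
  x <- seq(3, 60, by = 0.5)
  z <- compute_z("weight_for_age", "female", 48, x, ref)
  expect_true(all(diff(z) > 0))
})

test_that("out-of-range index errors name the indicator; missing weight is NA", {
  ref <- ncp_growth_reference()
  expect_error(compute_z("weight_for_age", "male", 200, 10, ref),
               "weight_for_age")
  expect_error(compute_z("weight_for_height", "male", 30, 10, ref),
               "weight_for_height")
  expect_true(is.na(compute_z("weight_for_age", "male", 24, NA, ref)))
  expect_error(compute_z("weight_for_age", "male", 24, -1, ref), "> 0")
})

test_that("measurement_for_z inverts compute_z, including the tails", {
  ref <- ncp_growth_reference()
  z_target <- c(-4.2, -3, -2.5, -1, 0, 1.7, 3.6)
  w <- measurement_for_z("weight_for_age", "female", 30, z_target, ref)
  expect_equal(compute_z("weight_for_age", "female", 30, w, ref), z_target,
               tolerance = 1e-9)
})

test_that("reference validation enforces schema and monotone index", {
  expect_error(as_growth_reference(data.frame(indicator = "weight_for_age")),
               "lacks columns")
  bad <- data.frame(indicator = "weight_for_age", sex = "male",
                    index = c(10, 10), L = 1, M = 9, S = 0.1)
  expect_error(as_growth_reference(bad), "strictly increasing")
  bad2 <- data.frame(indicator = "weight_for_age", sex = "male",
                     index = c(10, 12), L = 1, M = c(9, -1), S = 0.1)
  expect_error(as_growth_reference(bad2), "M > 0")
})
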