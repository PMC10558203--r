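# Piecewise-linear pH calibration and conversion.

test_that("calibration interpolates linearly and anchors at the reference", {
  cal <- build_calibration(data.frame(pH = c(6.4, 7.3), dff = c(-0.6, 0)))
  expect_equal(as.vector(dff_to_ph(-0.3, cal)), 6.85)
  expect_equal(as.vector(dff_to_ph(0, cal)), 7.3)
  expect_equal(cal_dff(cal, 6.85), -0.3)
})

test_that("non-monotone, duplicate and anchorless knot sets are rejected", {
  expect_error(build_calibration(
    data.frame(pH = c(6.4, 7.0, 7.3), dff = c(-0.6, -0.7, 0))), "monotone")
  expect_error(build_calibration(
    data.frame(pH = c(7.3, 7.3), dff = c(0, 0.1))), "duplicate")
  expect_error(build_calibration(
    data.frame(pH = c(6.4, 7.0), dff = c(-0.6, -0.2))), "reference knot")
  expect_error(build_calibration(data.frame(pH = 7.3, dff = 0)), "at least 2")
})

test_that("round trip through the sensor model is accurate and exact on knots", {
  knots <- c(6.4, 6.7, 7.0, 7.3)
  cal <- build_calibration(data.frame(pH = knots,
                                      dff = oracle_hill_dff(knots)))
  # identity on knot points exactly
  expect_equal(as.vector(dff_to_ph(oracle_hill_dff(knots), cal)), knots)
  # interpolation error matches the analytic bound for these knots: the
  # base-10 titration curve admits a worst case of 0.0205 pH near 6.55
  grid <- seq(6.4, 7.3, by = 0.005)
  rec <- dff_to_ph(oracle_hill_dff(grid), cal)
  err <- abs(as.vector(rec) - grid)
  expect_lt(max(err), 0.021)
  expect_gt(max(err), 0.019)  # the worst case is real, not a happy accident
  expect_equal(grid[which.max(err)], 6.555, tolerance = 0.05)
})

test_that("out-of-range values clamp to the end knots with per-sample flags", {
  cal <- build_calibration(data.frame(pH = c(6.4, 7.3), dff = c(-0.6, 0)))
  v <- dff_to_ph(c(-0.9, -0.3, 0.2), cal)
  expect_equal(as.vector(v)[1], 6.4)
  expect_equal(as.vector(v)[3], 7.3)
  expect_equal(attr(v, "clamped"), c(TRUE, FALSE, TRUE))
})

test_that("trace conversion warns unless corrected (or waived) and matches the
           simulator end to end at zero noise", {
  protocol <- short_protocol()
  sens <- sensor_params(noise_sd = 0, artifact_rate = 0)
  tr <- simulate_cell(opsin = fast_opsin(), sensor = sens,
                      protocol = protocol)
  dff <- (tr$F - tr$F[1]) / tr$F[1]
  raw <- structure(data.frame(t = tr$t, dff = dff), corrected = FALSE,
                   class = c("roi_trace", "data.frame"))
  knots <- seq(6.0, 7.4, by = 0.1)
  cal <- build_calibration(data.frame(pH = knots,
                                      dff = oracle_hill_dff(knots)))
  expect_warning(dff_to_ph(raw, cal), "uncorrected")
  got <- dff_to_ph(raw, cal, waive_correction = TRUE)
  expect_lt(max(abs(got$pH - tr$pH)), 0.02)
})

test_that("proton fold change follows the pH definition", {
  expect_equal(proton_fold_change(7.3, 6.76), 10^0.54)
  expect_gt(proton_fold_change(7.3, 6.76), 3)   # "approximately threefold"
  expect_equal(proton_fold_change(7.3, 7.3), 1)
  expect_equal(proton_fold_change(7.0, 6.0), 10)
})
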