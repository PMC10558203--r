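# Acidification half-times and exponential recovery fits.

test_that("half-time on analytic shapes: ramp, step, non-monotone dip", {
  t <- seq(0, 100, by = 2)
  ramp <- -0.4 * t / 100
  expect_equal(half_time_acid(ramp, c(0, 100), t = t)$t_half, 50)

  step <- ifelse(t >= 10, -0.4, 0)
  expect_equal(half_time_acid(step, c(0, 100), t = t)$t_half, 10,
               tolerance = 2)  # first sample at/after the step

  # dip to -0.4 at 30 s, recover to -0.1 at 60, dip to -0.35 at 100:
  # max decrease is 0.4; the half-crossing (-0.2) is on the first dip
  tt <- c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  y <- c(0, -0.15, -0.3, -0.4, -0.3, -0.2, -0.1, -0.15, -0.25, -0.3, -0.35)
  res <- half_time_acid(y, c(0, 100), t = tt)
  expect_equal(res$max_decrease, 0.4)
  # brute-force scan oracle for the first crossing of -0.2, interpolated
  cross <- which(-y >= 0.2)[1]
  t_oracle <- tt[cross - 1] + (0.2 - (-y)[cross - 1]) /
    ((-y)[cross] - (-y)[cross - 1]) * (tt[cross] - tt[cross - 1])
  expect_equal(res$t_half, t_oracle)
  expect_lt(res$t_half, 30)

  flat <- half_time_acid(rep(0.1, length(t)), c(0, 100), t = t)
  expect_null(flat$t_half)
  expect_match(flat$reason, "no acidification")
})

test_that("recovery fit recovers tau exactly on noiseless exponentials", {
  t <- seq(0, 150, by = 1.5)
  y <- 7.3 - 0.5 * exp(-t / 40)
  fit <- fit_recovery(y, c(0, 150), t = t)
  expect_equal(fit$tau, 40, tolerance = 1e-6)
  expect_equal(fit$t_half, 40 * log(2), tolerance = 1e-6)
  expect_equal(fit$t_half, 27.73, tolerance = 1e-3)
})

test_that("flat traces and tiny windows are refused with reasons", {
  t <- seq(0, 100, by = 5)
  flat <- fit_recovery(rep(6.9, length(t)), c(0, 100), t = t)
  expect_null(flat$tau)
  expect_match(flat$reason, "flat-trace")
  expect_error(fit_recovery(c(1, 2, 3), c(0, 2), t = c(0, 1, 2)),
               "at least 4 samples")
})

test_that("median recovered tau is within 5% across noisy replicates", {
  t <- seq(0, 150, by = 1.5)
  tau_true <- 40; amp <- 0.5
  taus <- vapply(1:50, function(s) {
    set.seed(s)
    y <- 7.3 - amp * exp(-t / tau_true) + rnorm(length(t), 0, 0.05 * amp)
    fit_recovery(y, c(0, 150), t = t)$tau
  }, numeric(1))
  expect_lt(abs(median(taus) - tau_true) / tau_true, 0.05)
})

test_that("roi_kinetics bundles the per-ROI summary", {
  t <- seq(0, 300, by = 1.5)
  pH <- ifelse(t <= 150, 7.3 - 0.5 * t / 150,
               6.8 + 0.35 * (1 - exp(-(t - 150) / 60)))
  k <- roi_kinetics(data.frame(t = t, pH = pH), c(0, 150), c(150, 300))
  expect_equal(k$t_half_acid, 75, tolerance = 1)
  expect_equal(k$tau_rec, 60, tolerance = 0.5)
  expect_equal(k$pH_min, 6.8, tolerance = 0.01)
})
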