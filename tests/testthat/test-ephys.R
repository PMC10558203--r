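# Photocurrent characterization chain.

test_that("moving average: identity, constancy, variance reduction, sign
           preservation", {
  x <- rnorm(100)
  expect_identical(smooth_trace(x, 1), x)
  expect_equal(smooth_trace(rep(3, 50), 7), rep(3, 50))
  set.seed(2)
  w <- 9; n <- 1e4
  noise <- rnorm(n)
  sm <- smooth_trace(noise, w)
  expect_equal(sd(sm[w:(n - w)]), 1 / sqrt(w), tolerance = 0.1)
  # smoothing never flips the net change of a monotone trace
  mono <- cumsum(abs(rnorm(200)))
  expect_gt(diff(range(smooth_trace(mono, 11))), 0)
  expect_equal(sign(diff(smooth_trace(mono, 11))[5]), 1)
  expect_error(smooth_trace(1:5, 4), "odd")
  expect_error(smooth_trace(1:5, 7), "larger than trace")
})

test_that("peak/steady extraction on constructed steps", {
  t <- seq(0, 500, by = 1)
  sag_free <- photocurrent_recording(t, ifelse(t >= 50 & t <= 450, -800, 0))
  ps <- peak_steady(sag_free, c(50, 450))
  expect_equal(ps$ratio, 1.00)

  # constructed 35% sag
  I <- ifelse(t >= 50 & t <= 450,
              -800 * (0.65 + 0.35 * exp(-(t - 50) / 20)), 0)
  ps2 <- peak_steady(photocurrent_recording(t, I), c(50, 450))
  expect_equal(ps2$ratio, 0.65, tolerance = 0.01)

  zero <- photocurrent_recording(t, rep(0, length(t)))
  expect_error(peak_steady(zero, c(50, 450)), "no photocurrent")
  expect_error(peak_steady(sag_free, c(50, 60)), "too short")
})

test_that("single-exponential tau fits: noiseless recovery, noisy median,
           misspecification flag", {
  t <- seq(0, 200, by = 0.2)
  I <- -500 * exp(-t / 17.6)
  rec <- photocurrent_recording(t, I, data.frame(t_on_ms = 0, t_off_ms = 0,
                                                 wavelength = 488,
                                                 intensity = 500))
  fit <- fit_tau(rec, "off", window = c(0, 200), smooth_window = 1)
  expect_equal(fit$tau_ms, 17.6, tolerance = 0.1)
  expect_false(fit$flagged)

  # SNR 10, slow closing, median over 50 seeded replicates within 5%
  t2 <- seq(0, 8000, by = 4)
  taus <- vapply(1:50, function(s) {
    set.seed(100 + s)
    I2 <- -1000 * exp(-t2 / 1950) + rnorm(length(t2), 0, 100)
    r <- photocurrent_recording(t2, I2,
                                data.frame(t_on_ms = 0, t_off_ms = 0,
                                           wavelength = 488, intensity = 500))
    fit_tau(r, "off", window = c(0, 8000))$tau_ms
  }, numeric(1))
  expect_lt(abs(median(taus) - 1950) / 1950, 0.05)

  # strongly bi-exponential input gets flagged by the residual threshold
  I3 <- -500 * (0.5 * exp(-t / 2) + 0.5 * exp(-t / 100))
  r3 <- photocurrent_recording(t, I3, data.frame(t_on_ms = 0, t_off_ms = 0,
                                                 wavelength = 488,
                                                 intensity = 500))
  f3 <- fit_tau(r3, "off", window = c(0, 200), smooth_window = 1)
  expect_true(f3$flagged)
})

test_that("EPD50 fitting: exact recovery, definitional half point, noisy
           median", {
  K <- 11.6
  P <- c(1, 2, 5, 10, 20, 50, 100, 200)
  ser <- data.frame(intensity = P, I_ss = 1000 * P / (P + K))
  fit <- fit_epd50(ser)
  expect_equal(fit$EPD50, K, tolerance = 1e-6 * K)
  expect_equal(fit$I_max * K / (K + K), fit$I_max / 2)  # P = EPD50 half point

  set.seed(8)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- ser$I_ss * (1 + rnorm(8, 0, 0.1))
    fit_epd50(data.frame(intensity = P, I_ss = noisy))$EPD50
  }, numeric(1))
  expect_lt(abs(median(errs) - K) / K, 0.1)

  narrow <- c(10, 12, 14, 16)
  expect_warning(fit_epd50(data.frame(intensity = narrow,
                                      I_ss = 1000 * narrow / (narrow + 12))),
                 "decade")
  expect_error(fit_epd50(data.frame(intensity = 1:3, I_ss = 1:3)), ">= 4")
})

test_that("reversal potential: interpolation, refusal, noisy bias", {
  iv <- data.frame(V = c(-70, 0, 40), I = 2 * (c(-70, 0, 40) - 10))
  expect_equal(reversal_potential(iv)$Vr_mV, 10)

  allneg <- data.frame(V = c(-70, -30), I = c(-5, -1))
  res <- reversal_potential(allneg)
  expect_null(res$Vr_mV)
  expect_match(res$reason, "refused")

  V <- seq(-70, 40, by = 10)
  biases <- vapply(1:50, function(s) {
    set.seed(s)
    I <- 3 * (V - 10) + rnorm(length(V), 0, 0.02 * 3 * 110)
    reversal_potential(data.frame(V = V, I = I))$Vr_mV - 10
  }, numeric(1))
  expect_lt(abs(mean(biases)), 1)
})

test_that("Nernst shift arithmetic", {
  expect_equal(nernst_shift(120, 1, 1, 298), -122.9, tolerance = 0.05)
  expect_equal(nernst_shift(100, 100), 0)
  # antisymmetric under swapping concentrations
  expect_equal(nernst_shift(120, 1), -nernst_shift(1, 120))
  # divalent ion halves the shift
  expect_equal(nernst_shift(10, 100, 2), nernst_shift(10, 100, 1) / 2)
  expect_error(nernst_shift(0, 1), "> 0")
})

test_that("action spectrum normalizes to blue and censors below the floor", {
  cur <- c("488" = -800, "532" = -400, "561" = -160, "594" = -38.4,
           "640" = -1)
  sp <- action_spectrum(cur, floor = 0.003)
  expect_equal(sp$relative[sp$wavelength == 488], 1)
  expect_equal(sp$relative[sp$wavelength == 561], 0.2)
  expect_true(sp$censored[sp$wavelength == 640])
  expect_match(sp$display[sp$wavelength == 640], "< 0.003")
  expect_error(action_spectrum(c("532" = -1)), "reference wavelength")
})

test_that("crosstalk fractions", {
  expect_equal(crosstalk(-800, -800, 0),
               list(activation_fraction = 0, inactivation_fraction = 0))
  expect_equal(crosstalk(-800, -480, 0)$inactivation_fraction, 0.4)
  expect_equal(crosstalk(-800, -800, -40)$activation_fraction, 0.05)
  expect_error(crosstalk(0, -1, 0), "detection floor")
})

test_that("characterization recovers the generating parameters", {
  for (nm in c("cheriff", "chr2_3m", "pscatch2")) {
    op <- opsin_preset(nm)
    ch <- characterize_opsin(op)
    expect_equal(ch$Vr_mV, op$E_ops_mV, tolerance = 1e-6)
    expect_lt(abs(ch$tau_on_fastest_ms - op$tau_on_sat_ms) /
                op$tau_on_sat_ms, 0.05)
    expect_lt(abs(ch$tau_off_ms - op$tau_off_ms) / op$tau_off_ms, 0.05)
    expect_lt(abs(ch$EPD50_mW_cm2 - op$EPD50_mW_cm2) / op$EPD50_mW_cm2, 0.1)
    # modelled tau_on at the EPD50 doubles the saturating value
    expect_equal(ch$tau_on_at_EPD50_ms, 2 * op$tau_on_sat_ms,
                 tolerance = 0.1 * op$tau_on_sat_ms)
    expect_lt(abs(ch$peak_ratio - op$desensitization_ratio), 0.01)
  }
})
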