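# Compartment forward model: gate, voltage, pH, fluorescence, full simulation.

test_that("geometry closed forms and validation", {
  sph <- compartment_geometry("sphere", 10)
  expect_equal(sph$surface_to_volume, 0.3)
  expect_equal(sph$volume_um3, 4 / 3 * pi * 1000)
  cyl <- compartment_geometry("cylinder", 1, 40)
  expect_equal(cyl$surface_to_volume, 2)
  expect_error(compartment_geometry("sphere", -1), "radius")
  expect_error(compartment_geometry("cylinder", 1), "length_um")
})

test_that("gate reaches half activation at the EPD50 and saturates", {
  op <- fast_opsin()
  t <- seq(0, 1, by = 1e-3)
  a <- opsin_gate(op, intensity = op$EPD50_mW_cm2, wavelength = 488, t = t)
  expect_equal(tail(a, 1), 0.5, tolerance = 1e-6)
  a_sat <- opsin_gate(op, intensity = 100 * op$EPD50_mW_cm2,
                      wavelength = 488, t = t)
  expect_gt(tail(a_sat, 1), 0.99)
})

test_that("gate closes as a single exponential with tau_off", {
  op <- fast_opsin()
  t <- seq(0, 0.2, by = 1e-5)
  # drive to full activation, then light off at t0 = 0.1 s
  light <- t < 0.1
  a <- opsin_gate(op, 1e6, 488, t, light = light, a0 = 0)
  t0 <- 0.1
  a0 <- a[which.min(abs(t - t0))]
  k <- which.min(abs(t - (t0 + op$tau_off_ms / 1000)))
  expect_equal(a[k] / a0, exp(-1), tolerance = 1e-5)
})

test_that("unknown wavelengths error instead of silently contributing zero", {
  op <- fast_opsin()
  expect_error(opsin_gate(op, 100, 999, seq(0, 1, 0.01)),
               "absent from opsin spectrum")
})

test_that("voltage relaxes to E_K without activation and to the
           conductance-weighted steady state with it", {
  op <- fast_opsin(g_max = 3)  # g_max = g_leak below
  phys <- physiology_params(g_leak_nS = 3, E_K_mV = -70)
  dt <- 1e-4
  V <- 0
  for (i in 1:20000) V <- step_voltage(V, 0, op, phys, dt)
  expect_equal(V, -70, tolerance = 1e-6)

  # a = 0.5, g_max = g_leak, E_K = -70, E_ops = +10:
  # V_inf = (-70 + 0.5*10) / 1.5 = -43.333...
  op2 <- opsin_params(3, 10, 0.5, 22, 4.5, 16, spectrum = c("488" = 1))
  V <- -70
  for (i in 1:20000) V <- step_voltage(V, 0.5, op2, phys, dt)
  expect_equal(V, (-70 * 1 + 10 * 0.5) / 1.5, tolerance = 1e-6)

  # dominant opsin conductance pulls V to E_ops
  op3 <- opsin_params(3000, 10, 0.5, 22, 4.5, 16, spectrum = c("488" = 1))
  V <- -70
  dt3 <- 1e-6
  for (i in 1:50000) V <- step_voltage(V, 1, op3, phys, dt3)
  expect_equal(V, 10, tolerance = 0.1)
})

test_that("voltage step errors above the stability bound, naming it", {
  op <- fast_opsin()
  phys <- physiology_params()
  bound <- 2 * phys$C_m_pF / (phys$g_leak_nS + op$g_max_nS) / 1000
  expect_error(step_voltage(-70, 0.5, op, phys, bound * 1.01),
               "stability bound")
  expect_silent(step_voltage(-70, 0.5, op, phys, bound * 0.99))
})

test_that("Euler voltage trace matches the closed-form exponential", {
  op <- fast_opsin()
  phys <- physiology_params()
  a <- 0.4
  g_tot <- phys$g_leak_nS + op$g_max_nS * a
  dt <- 1e-4 * phys$C_m_pF / g_tot / 1000
  n <- 20000
  V <- numeric(n + 1); V[1] <- -70
  for (k in 1:n) V[k + 1] <- step_voltage(V[k], a, op, phys, dt)
  t <- (0:n) * dt
  V_exact <- oracle_voltage(t, -70, a, phys$g_leak_nS, op$g_max_nS,
                            phys$E_K_mV, op$E_ops_mV, phys$C_m_pF)
  expect_lt(max(abs(V - V_exact)) / abs(diff(range(V_exact))), 1e-4)
})

test_that("pH bookkeeping matches the analytic integral of the proton current", {
  op <- fast_opsin()
  geom <- compartment_geometry("sphere", 10)
  phys <- physiology_params(k_rec = 0)
  V <- -40; a <- 0.6; dt <- 1e-3; n <- 5000
  pH <- 7.3
  for (k in 1:n) pH <- step_ph(pH, V, a, op, geom, phys, dt)
  I_H <- op$f_H * op$g_max_nS * a * (V - op$E_ops_mV) * 1e-12  # A, inward
  dpH_analytic <- I_H * (n * dt) / (96485.33212 * geom$volume_L *
                                      phys$beta_buff)
  expect_equal(pH - 7.3, dpH_analytic, tolerance = 1e-6)
  expect_lt(pH, 7.3)
})

test_that("no proton pathway means no pH change; extrusion relaxes pH back", {
  op0 <- fast_opsin(f_H = 0)
  geom <- compartment_geometry("sphere", 10)
  phys <- physiology_params(k_rec = 0.01)
  pH <- 7.3
  for (k in 1:1000) pH <- step_ph(pH, -20, 1, op0, geom, phys, 1e-3)
  expect_equal(pH, 7.3)

  # I_H = 0, displaced pH recovers with time constant 1/k_rec
  pH <- 6.8; dt <- 1e-3
  n <- round(1 / phys$k_rec / dt)  # one time constant
  for (k in 1:n) pH <- step_ph(pH, -70, 0, op0, geom, phys, dt)
  expect_equal(7.3 - pH, 0.5 * exp(-1), tolerance = 1e-3)
})

test_that("initial acidification rate scales as surface-to-volume at fixed
           current density", {
  phys <- physiology_params(k_rec = 0)
  cyl <- compartment_geometry("cylinder", 1, 40)
  sph <- compartment_geometry("sphere", 10)
  g_density <- 0.01  # nS per um^2
  op_cyl <- fast_opsin(g_max = g_density * cyl$area_um2)
  op_sph <- fast_opsin(g_max = g_density * sph$area_um2)
  dt <- 1e-4; V <- -40; a <- 1
  rate_cyl <- (step_ph(7.3, V, a, op_cyl, cyl, phys, dt) - 7.3) / dt
  rate_sph <- (step_ph(7.3, V, a, op_sph, sph, phys, dt) - 7.3) / dt
  expect_equal(rate_cyl / rate_sph,
               cyl$surface_to_volume / sph$surface_to_volume,
               tolerance = 1e-9)
  expect_equal(rate_cyl / rate_sph, (2 / 1) / (3 / 10), tolerance = 1e-9)
})

test_that("fluorescence rendering: half-protonation point and identity", {
  sens <- sensor_params(pKa = 7.5, F_max = 1000, artifact_rate = 0,
                        noise_sd = 0)
  expect_equal(render_fluorescence(7.5, sens), 500)
  Fv <- render_fluorescence(rep(7.0, 50), sens)
  expect_true(all(Fv == Fv[1]))  # constant pH, no artifact, no noise
  expect_error(render_fluorescence(c(7, NA), sens), "finite")
})

test_that("opsin-negative control shows the calibrated +0.11 dFF photoartifact", {
  protocol <- build_protocol(0.5, 1, 150, 150, stim_intensity = 500)
  sens <- sensor_params(noise_sd = 0)
  t <- seq(0, 300, by = 0.5)
  Fv <- render_fluorescence(rep(7.3, length(t)), sens, protocol = protocol,
                            t = t)
  dff <- (Fv - Fv[1]) / Fv[1]
  expect_equal(dff[t == 150], 0.11, tolerance = 1e-9)
  expect_equal(dff[t == 300], 0.11, tolerance = 1e-9)  # no blue in recovery
})

test_that("full simulation: defaults acidify into the expected envelope,
           zero proton fraction does not, same seed reproduces bitwise", {
  protocol <- build_protocol(0.5, 1, 150, 150)
  sens <- sensor_params(noise_sd = 0.004)
  tr <- simulate_cell(sensor = sens, protocol = protocol, seed = 7)
  i150 <- which.min(abs(tr$t - 150))
  drop <- 7.3 - tr$pH[i150]
  expect_gt(drop, 0.3)
  expect_lt(drop, 0.8)
  # pH is non-increasing during stimulation when extrusion is off
  phys0 <- physiology_params(k_rec = 0)
  tr0 <- simulate_cell(phys = phys0, protocol = build_protocol(0.5, 1, 15, 0))
  expect_true(all(diff(tr0$pH) <= 1e-12))

  trH0 <- simulate_cell(opsin = fast_opsin(f_H = 0), protocol = protocol)
  expect_lt(max(abs(trH0$pH - 7.3)), 0.02)

  tr2 <- simulate_cell(sensor = sens, protocol = protocol, seed = 7)
  expect_identical(tr$F, tr2$F)
  expect_identical(tr$pH, tr2$pH)
  tr3 <- simulate_cell(sensor = sens, protocol = protocol, seed = 8)
  expect_false(identical(tr3$F, tr$F))
})
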