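# Gap-junction monolayer: patterns, field updates, contrast logic.

test_that("stripe patterns quantize correctly to the lattice", {
  g <- monolayer_grid(nx = 100, ny = 10)  # 2000 um field at 20-um pitch
  p <- stripe_pattern(g, 95, 95)
  frac <- mean(p[1, ])
  # quantization: the 190-um period spans 9.5 rows, so the illuminated
  # fraction can deviate by up to one row per period
  expect_lt(abs(frac - 0.5), 20 / 190)

  # brute-force run count oracle over cell centres
  centres <- (seq_len(100) - 0.5) * 20
  on <- (centres %% 190) < 95
  runs <- rle(on)
  n_stripes <- sum(runs$values)
  expect_true(n_stripes %in% c(floor(2000 / 190), floor(2000 / 190) + 1))
  expect_equal(sum(p[1, ]), sum(on))

  expect_true(all(stripe_pattern(g, 95, 0)))  # gap 0: all on
  half <- stripe_pattern(g, 100, 100)  # 10-row period: exact half split
  expect_equal(mean(half), 0.5)
  expect_error(stripe_pattern(g, 10, 10), "unresolvable")
})

test_that("uniform illumination of a homogeneous grid keeps V uniform", {
  g <- monolayer_grid(nx = 12, ny = 12)
  p <- stripe_pattern(g, 100, 0)
  sim <- simulate_monolayer(g, p, t_stim_s = 1)
  expect_lt(diff(range(sim$V)), 1e-6)
})

test_that("gap-junction currents conserve total charge", {
  g <- monolayer_grid(nx = 10, ny = 8,
                      phys = physiology_params(g_leak_nS = 0, k_rec = 0))
  set.seed(3)
  g$V <- matrix(rnorm(80, -40, 15), 8, 10)
  dark <- illumination_pattern(matrix(FALSE, 8, 10), g$pitch_um)
  tot0 <- sum(g$V)
  for (i in 1:50) g <- step_field(g, dark, dt = 5e-6)
  # with zero leak and no light, only gap currents act: sum(V) is invariant
  expect_equal(sum(g$V), tot0, tolerance = 1e-9 * abs(tot0))
})

test_that("lateral voltage decay matches the cable length constant", {
  g <- monolayer_grid(nx = 121, ny = 6)
  mask <- matrix(FALSE, 6, 121); mask[, 61] <- TRUE
  sim <- simulate_monolayer(g, illumination_pattern(mask, 20), t_stim_s = 0.1)
  dep <- sim$V[3, ] - g$phys$E_K_mV
  d_cells <- 5:25
  prof <- dep[61 + d_cells]
  fit <- stats::lm(log(prof) ~ d_cells)
  lambda_fit <- -g$pitch_um / unname(coef(fit)[2])
  lambda_true <- g$pitch_um * sqrt(g$g_gap_nS / g$phys$g_leak_nS)
  expect_equal(lambda_fit, lambda_true, tolerance = 0.05)
})

test_that("mirror-symmetric patterns give mirror-symmetric fields", {
  g <- monolayer_grid(nx = 30, ny = 8)
  mask <- matrix(FALSE, 8, 30); mask[, 5:8] <- TRUE
  s1 <- simulate_monolayer(g, illumination_pattern(mask, 20), t_stim_s = 2)
  s2 <- simulate_monolayer(g, illumination_pattern(mask[, 30:1], 20),
                           t_stim_s = 2)
  expect_equal(s1$V, s2$V[, 30:1], tolerance = 1e-10)
  expect_equal(s1$dpH, s2$dpH[, 30:1], tolerance = 1e-12)
})

test_that("without gap-junction proton exchange, only illuminated cells
           acidify while voltage spreads", {
  g <- monolayer_grid(nx = 60, ny = 10)
  p <- stripe_pattern(g, 95, 95)
  sim <- simulate_monolayer(g, p, t_stim_s = 5)
  on <- unclass(p); off <- !on
  expect_lt(max(sim$dpH[on]), 0)             # illuminated cells acidify
  expect_identical(max(abs(sim$dpH[off])), 0)  # no proton path off-stripe
  vc <- voltage_contrast(sim)
  expect_gt(vc$off_on_fraction, 0.85)
})

test_that("acidification contrast distinguishes opsin-borne protons from the
           voltage-gated counterfactual", {
  g <- monolayer_grid(nx = 60, ny = 10)
  p <- stripe_pattern(g, 95, 95)
  sim <- simulate_monolayer(g, p, t_stim_s = 5)
  ac <- acidification_contrast(sim)
  expect_gte(ac$ratio, 10)
  expect_false(ac$no_signal)

  simv <- simulate_monolayer(g, p, t_stim_s = 5,
                             proton_mode = "voltage_gated")
  acv <- acidification_contrast(simv)
  expect_lt(abs(acv$ratio - 1), 0.2)

  # zero stimulation: flagged as no-signal with unit ratio
  dark_grid <- monolayer_grid(nx = 10, ny = 6)
  dark <- simulate_monolayer(dark_grid, stripe_pattern(dark_grid, 95, 95),
                             t_stim_s = 1, intensity = 0)
  acd <- acidification_contrast(dark)
  expect_true(acd$no_signal)
  expect_equal(acd$ratio, 1)

  expect_error(acidification_contrast(
    simulate_monolayer(dark_grid, stripe_pattern(dark_grid, 95, 0),
                       t_stim_s = 1)), "both illuminated and dark")
})

test_that("step_field enforces its coupled stability bound", {
  g <- monolayer_grid(nx = 6, ny = 6)
  p <- stripe_pattern(g, 95, 95)
  bound <- 2 * g$phys$C_m_pF /
    (g$phys$g_leak_nS + g$opsin$g_max_nS + 8 * g$g_gap_nS) / 1000
  expect_error(step_field(g, p, dt = bound * 1.1), "stability bound")
  expect_s3_class(step_field(g, p, dt = bound * 0.9), "monolayer_grid")
})
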