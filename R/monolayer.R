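#' Gap-junction-coupled monolayer grid
#'
#' Square lattice of lumped cells with 4-neighbor ohmic gap-junction
#' coupling and no-flux boundaries. The steady-state electrotonic length
#' constant of the sheet is `pitch * sqrt(g_gap / g_leak)`; the defaults
#' (pitch 20 um, g_gap 450 nS, g_leak 2 nS) give ~300 um, the scale over
#' which depolarization spreads in a confluent, inward-rectifier-polarized
#' monolayer.
#'
#' @param nx,ny grid dimensions (cells).
#' @param pitch_um cell pitch (um per cell).
#' @param g_gap_nS gap-junction conductance per neighbor pair (nS),
#'   symmetric by construction.
#' @param opsin an [opsin_params()] shared by expressing cells.
#' @param phys a [physiology_params()] shared by all cells.
#' @param cell_volume_L cytosolic volume per cell (litres).
#' @param express logical ny x nx matrix of opsin expression (default all).
#' @return A `monolayer_grid` with state matrices `V` (mV), `pH` and
#'   activation `a`.
#' @export
monolayer_grid <- function(nx = 100, ny = 100, pitch_um = 20, g_gap_nS = 450,
                           opsin = opsin_preset("cheriff"),
                           phys = physiology_params(g_leak_nS = 2),
                           cell_volume_L = 4e-12, express = NULL) {
  if (pitch_um <= 0) stop("pitch_um must be > 0", call. = FALSE)
  if (g_gap_nS < 0) stop("g_gap_nS must be >= 0", call. = FALSE)
  if (is.null(express)) express <- matrix(TRUE, ny, nx)
  stopifnot(identical(dim(express), c(as.integer(ny), as.integer(nx))))
  structure(list(nx = nx, ny = ny, pitch_um = pitch_um, g_gap_nS = g_gap_nS,
                 opsin = opsin, phys = phys, cell_volume_L = cell_volume_L,
                 express = express,
                 V = matrix(phys$E_K_mV, ny, nx),
                 pH = matrix(phys$pH_rest, ny, nx),
                 a = matrix(0, ny, nx)),
            class = "monolayer_grid")
}

#' @export
print.monolayer_grid <- function(x, ...) {
  lambda <- x$pitch_um * sqrt(x$g_gap_nS / x$phys$g_leak_nS)
  cat(sprintf("Monolayer grid %d x %d cells, pitch %g um, g_gap %g nS (lambda ~ %.0f um)\n",
              x$nx, x$ny, x$pitch_um, x$g_gap_nS, lambda))
  cat(sprintf("  V in [%.2f, %.2f] mV; pH in [%.3f, %.3f]\n",
              min(x$V), max(x$V), min(x$pH), max(x$pH)))
  invisible(x)
}

#' Wrap a binary mask as an illumination pattern
#'
#' @param mask logical matrix matching the grid (TRUE = illuminated).
#' @param pitch_um cell pitch (um), for bookkeeping.
#' @return An `illumination_pattern`.
#' @export
illumination_pattern <- function(mask, pitch_um = NA_real_) {
  storage.mode(mask) <- "logical"
  structure(mask, pitch_um = pitch_um, class = c("illumination_pattern",
                                                 "matrix", "array"))
}

#' Striped illumination pattern
#'
#' Periodic stripes of illuminated cells (stripe period = on-width + gap),
#' quantized to the cell lattice by cell-centre position.
#'
#' @param grid a [monolayer_grid()].
#' @param on_width_um illuminated stripe width (um, > 0).
#' @param gap_um dark gap between stripes (um, >= 0; 0 gives an all-on mask).
#' @param orientation `"vertical"` (stripes run along y, varying along x) or
#'   `"horizontal"`.
#' @return An `illumination_pattern` (logical ny x nx matrix).
#' @export
stripe_pattern <- function(grid, on_width_um, gap_um,
                           orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  if (on_width_um <= 0 || gap_um < 0) {
    stop("on_width_um must be > 0 and gap_um >= 0", call. = FALSE)
  }
  period <- on_width_um + gap_um
  if (gap_um > 0 && period < 2 * grid$pitch_um) {
    stop(sprintf("unresolvable pattern: stripe period %g um < 2 * pitch = %g um",
                 period, 2 * grid$pitch_um), call. = FALSE)
  }
  n <- if (orientation == "vertical") grid$nx else grid$ny
  centres <- (seq_len(n) - 0.5) * grid$pitch_um
  on <- if (gap_um == 0) rep(TRUE, n) else (centres %% period) < on_width_um
  mask <- if (orientation == "vertical") {
    matrix(on, grid$ny, grid$nx, byrow = TRUE)
  } else {
    matrix(on, grid$ny, grid$nx)
  }
  illumination_pattern(mask, grid$pitch_um)
}

# 4-neighbor sum with replicated edges (no-flux boundary)
nb_sum <- function(M) {
  rbind(M[1, , drop = FALSE], M[-nrow(M), , drop = FALSE]) +
    rbind(M[-1, , drop = FALSE], M[nrow(M), , drop = FALSE]) +
    cbind(M[, 1, drop = FALSE], M[, -ncol(M), drop = FALSE]) +
    cbind(M[, -1, drop = FALSE], M[, ncol(M), drop = FALSE])
}

# default counterfactual voltage-gated proton conductance
vg_defaults <- function() {
  list(g_nS = 2, V_half_mV = -50, slope_mV = 5, f_H = 1, E_mV = 10)
}

# per-cell proton current field (pA); negative = inward (acidifying)
proton_current_field <- function(V, a, grid, proton_mode, vg) {
  if (proton_mode == "opsin") {
    grid$opsin$f_H * grid$opsin$g_max_nS * a * (V - grid$opsin$E_ops_mV)
  } else {
    gate <- 1 / (1 + exp(-(V - vg$V_half_mV) / vg$slope_mV))
    vg$f_H * vg$g_nS * gate * (V - vg$E_mV)
  }
}

#' One explicit-Euler step of the coupled monolayer field
#'
#' Per cell: `C_m dV_i/dt = -g_leak (V_i - E_K) - g_max a_i (V_i - E_ops) +
#' g_gap * sum_j (V_j - V_i)` over the 4 neighbors (no-flux boundary), with
#' the opsin gated only in illuminated, expressing cells. pH follows the same
#' proton-flux law as [step_ph()] using each cell's own proton current, plus
#' optional gap-junction proton exchange at rate `k_gapH` (default 0: proton
#' diffusion through gap junctions is orders of magnitude slower than voltage
#' spread). In the counterfactual `"voltage_gated"` mode the proton path is
#' rerouted through a voltage-gated conductance present in every cell — the
#' hypothesis that patterned-illumination experiments are designed to reject.
#'
#' @param grid a [monolayer_grid()].
#' @param pattern an [illumination_pattern()] matching the grid.
#' @param dt time step (s); must satisfy the coupled stability bound
#'   `2 C_m / (g_leak + g_max + 8 g_gap)`.
#' @param intensity,wavelength stimulation light (mW cm^-2, nm).
#' @param k_gapH gap-junction proton exchange rate constant (s^-1 per
#'   neighbor pH difference).
#' @param proton_mode `"opsin"` (protons flow through the opsin) or
#'   `"voltage_gated"` (counterfactual).
#' @param vg counterfactual conductance parameters, see source of
#'   `vg_defaults`.
#' @return The updated `monolayer_grid`.
#' @export
step_field <- function(grid, pattern, dt, intensity = 500, wavelength = 488,
                       k_gapH = 0, proton_mode = c("opsin", "voltage_gated"),
                       vg = vg_defaults()) {
  proton_mode <- match.arg(proton_mode)
  phys <- grid$phys; opsin <- grid$opsin
  bound <- 2 * phys$C_m_pF /
    (phys$g_leak_nS + opsin$g_max_nS + 8 * grid$g_gap_nS) / 1000
  if (!is.finite(dt) || dt <= 0 || dt > bound) {
    stop(sprintf("dt = %g s violates the coupled stability bound 2*C_m/(g_leak + g_max + 8*g_gap) = %g s",
                 dt, bound), call. = FALSE)
  }
  lit <- unclass(pattern) & grid$express

  # gate: first-order toward the (desensitized) steady target where lit
  s <- spectrum_at(opsin, wavelength)
  a_target <- ifelse(lit, s * intensity / (intensity + opsin$EPD50_mW_cm2) *
                       opsin$desensitization_ratio, 0)
  tau_on <- opsin$tau_on_sat_ms * (1 + opsin$EPD50_mW_cm2 /
                                     max(intensity, 1e-12)) / 1000
  tau <- ifelse(lit, tau_on, opsin$tau_off_ms / 1000)
  a <- a_target + (grid$a - a_target) * exp(-dt / tau)

  V <- grid$V
  I_gap <- grid$g_gap_nS * (nb_sum(V) - 4 * V)  # pA; sums to zero over grid
  dV <- dt * 1e3 * (-phys$g_leak_nS * (V - phys$E_K_mV) -
                      opsin$g_max_nS * a * (V - opsin$E_ops_mV) + I_gap) /
    phys$C_m_pF
  V_new <- V + dV

  I_H <- proton_current_field(V, a, grid, proton_mode, vg)
  conv <- 1e-12 / (.FARADAY * grid$cell_volume_L * phys$beta_buff)
  pH <- grid$pH
  dpH <- dt * (pmin(I_H, 0) * conv + phys$k_rec * (phys$pH_rest - pH))
  if (k_gapH > 0) dpH <- dpH + dt * k_gapH * (nb_sum(pH) - 4 * pH)

  grid$a <- a; grid$V <- V_new; grid$pH <- pH + dpH
  grid
}

#' Simulate a monolayer under patterned illumination
#'
#' Exploits the timescale separation between voltage spread (milliseconds)
#' and acidification (seconds): first the voltage field is equilibrated with
#' the explicit [step_field()] update (gate held at its steady target), then
#' pH is integrated over the stimulation period with the steady voltage
#' field held fixed (exactly, per cell, when `k_gapH = 0`; explicit Euler
#' otherwise).
#'
#' @inheritParams step_field
#' @param t_stim_s stimulation duration over which pH accumulates (s).
#' @param duty fraction of the stimulation period the light is actually on
#'   (interleaved protocols; 1 = continuous).
#' @param dt voltage-equilibration step (s); default half the stability bound.
#' @param v_equil_s voltage equilibration horizon (s); several multiples of
#'   the slowest membrane time constant `C_m/g_leak`.
#' @param dt_ph pH step (s) used only when `k_gapH > 0`.
#' @return A `monolayer_sim`: list with the steady `V` field (mV), activation
#'   `a`, `pH` (final), `dpH` (final minus resting), the `pattern`, mode and
#'   the voltage residual (max |dV/dt| at the end of equilibration, mV/s).
#' @export
simulate_monolayer <- function(grid, pattern, t_stim_s = 13.5,
                               intensity = 500, wavelength = 488, duty = 1,
                               proton_mode = c("opsin", "voltage_gated"),
                               k_gapH = 0, vg = vg_defaults(),
                               dt = NULL, v_equil_s = NULL, dt_ph = 0.01) {
  proton_mode <- match.arg(proton_mode)
  phys <- grid$phys; opsin <- grid$opsin
  bound <- 2 * phys$C_m_pF /
    (phys$g_leak_nS + opsin$g_max_nS + 8 * grid$g_gap_nS) / 1000
  if (is.null(dt)) dt <- bound / 2
  if (is.null(v_equil_s)) v_equil_s <- 8 * phys$C_m_pF / phys$g_leak_nS / 1000
  lit <- unclass(pattern) & grid$express
  s <- spectrum_at(opsin, wavelength)
  a <- ifelse(lit, s * intensity / (intensity + opsin$EPD50_mW_cm2) *
                opsin$desensitization_ratio, 0)

  # phase 1: voltage relaxation to the patterned steady state
  V <- grid$V
  g_self <- phys$g_leak_nS + opsin$g_max_nS * a
  drive <- phys$g_leak_nS * phys$E_K_mV + opsin$g_max_nS * a * opsin$E_ops_mV
  n1 <- max(1L, ceiling(v_equil_s / dt))
  fac <- dt * 1e3 / phys$C_m_pF
  for (k in seq_len(n1)) {
    I_gap <- grid$g_gap_nS * (nb_sum(V) - 4 * V)
    dV <- fac * (drive - g_self * V + I_gap)
    V <- V + dV
  }
  residual <- max(abs(dV)) / dt  # mV/s

  # phase 2: slow pH accumulation on the frozen voltage field
  I_H <- pmin(proton_current_field(V, a, grid, proton_mode, vg), 0) * duty
  conv <- 1e-12 / (.FARADAY * grid$cell_volume_L * phys$beta_buff)
  pH0 <- grid$pH
  if (k_gapH > 0) {
    pH <- pH0
    nst <- max(1L, ceiling(t_stim_s / dt_ph))
    h <- t_stim_s / nst
    for (k in seq_len(nst)) {
      pH <- pH + h * (I_H * conv + phys$k_rec * (phys$pH_rest - pH) +
                        k_gapH * (nb_sum(pH) - 4 * pH))
    }
  } else if (phys$k_rec > 0) {
    target <- phys$pH_rest + I_H * conv / phys$k_rec
    pH <- target + (pH0 - target) * exp(-phys$k_rec * t_stim_s)
  } else {
    pH <- pH0 + I_H * conv * t_stim_s
  }

  structure(list(V = V, a = a, pH = pH, dpH = pH - pH0, pattern = pattern,
                 grid = grid, proton_mode = proton_mode, t_stim_s = t_stim_s,
                 residual_mV_per_s = residual),
            class = "monolayer_sim")
}

#' @export
print.monolayer_sim <- function(x, ...) {
  cat(sprintf("Monolayer simulation (%s proton path), %g s stimulation\n",
              x$proton_mode, x$t_stim_s))
  cat(sprintf("  V: [%.2f, %.2f] mV; dpH: [%.4f, %.4f]\n",
              min(x$V), max(x$V), min(x$dpH), max(x$dpH)))
  invisible(x)
}

#' On-stripe vs off-stripe acidification contrast
#'
#' Compares the mean pH change in directly illuminated cells against cells
#' depolarized only through gap junctions. A documented floor (1e-4 pH
#' units) guards the ratio against division by zero; if both sides are below
#' the floor the ratio is reported as 1 with a no-signal flag.
#'
#' @param sim a [simulate_monolayer()] result.
#' @param pattern optional pattern (defaults to the one simulated).
#' @param floor smallest |dpH| treated as signal (pH units).
#' @return List with `dpH_on`, `dpH_off` (mean |dpH|), `ratio` (on/off) and
#'   `no_signal`.
#' @export
acidification_contrast <- function(sim, pattern = sim$pattern,
                                   floor = 1e-4) {
  mask <- unclass(pattern) & sim$grid$express
  off <- !unclass(pattern) & sim$grid$express
  if (!any(mask) || !any(off)) {
    stop("pattern must contain both illuminated and dark cells", call. = FALSE)
  }
  on_mean <- mean(abs(sim$dpH[mask]))
  off_mean <- mean(abs(sim$dpH[off]))
  no_signal <- on_mean < floor && off_mean < floor
  ratio <- if (no_signal) 1 else max(on_mean, floor) / max(off_mean, floor)
  list(dpH_on = on_mean, dpH_off = off_mean, ratio = ratio,
       no_signal = no_signal)
}

#' On-stripe vs off-stripe depolarization contrast
#'
#' @param sim a [simulate_monolayer()] result.
#' @param pattern optional pattern (defaults to the one simulated).
#' @return List with mean depolarization (mV above the resting potential)
#'   on- and off-stripe and their off/on fraction.
#' @export
voltage_contrast <- function(sim, pattern = sim$pattern) {
  mask <- unclass(pattern) & sim$grid$express
  off <- !unclass(pattern) & sim$grid$express
  if (!any(mask) || !any(off)) {
    stop("pattern must contain both illuminated and dark cells", call. = FALSE)
  }
  rest <- sim$grid$phys$E_K_mV
  dep_on <- mean(sim$V[mask] - rest)
  dep_off <- mean(sim$V[off] - rest)
  list(depol_on_mV = dep_on, depol_off_mV = dep_off,
       off_on_fraction = dep_off / dep_on)
}
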