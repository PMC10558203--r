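#' One explicit-Euler step of the membrane-voltage equation
#'
#' Integrates `C_m dV/dt = -g_leak (V - E_K) - g_max a (V - E_ops)` by one
#' explicit Euler step. The step errors if `dt` exceeds the stability bound
#' `2 C_m / (g_leak + g_max)` (with conductances in nS and capacitance in pF
#' that bound is `2 C_m / g` milliseconds).
#'
#' @param V membrane voltage (mV).
#' @param activation opsin activation in \[0, 1\].
#' @param opsin an [opsin_params()] object.
#' @param phys a [physiology_params()] object.
#' @param dt time step (s).
#' @return Updated voltage (mV). Vectorized over `V`/`activation`.
#' @export
step_voltage <- function(V, activation, opsin, phys, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  bound <- 2 * phys$C_m_pF / (phys$g_leak_nS + opsin$g_max_nS) / 1000
  if (dt > bound) {
    stop(sprintf(paste0("dt = %g s violates the explicit-Euler stability ",
                        "bound 2*C_m/(g_leak + g_max) = %g s"), dt, bound),
         call. = FALSE)
  }
  g_ops <- opsin$g_max_nS * activation
  # pF, nS, mV: dV/dt [mV/s] = 1e3 * I[pA] / C_m[pF]
  V + dt * 1e3 * (-phys$g_leak_nS * (V - phys$E_K_mV) -
                    g_ops * (V - opsin$E_ops_mV)) / phys$C_m_pF
}

#' One explicit-Euler step of intracellular pH
#'
#' The proton component of the photocurrent is
#' `I_H = f_H * g_max * a * (V - E_ops)` (pA); only the inward (negative)
#' fraction acidifies. pH then follows
#' `d(pH)/dt = I_H / (F * Volume * beta) + k_rec * (pH_rest - pH)`,
#' where the first term is the membrane proton flux divided by compartment
#' volume and buffering capacity (equivalently, proportional to the
#' surface-to-volume ratio at fixed current density), and the second is
#' first-order extrusion toward resting pH.
#'
#' @inheritParams step_voltage
#' @param pH current pH.
#' @param geom a [compartment_geometry()].
#' @return Updated pH. Vectorized over `pH`/`V`/`activation`.
#' @export
step_ph <- function(pH, V, activation, opsin, geom, phys, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (phys$beta_buff <= 0) {
    stop("non-physical buffering capacity: beta_buff must be > 0",
         call. = FALSE)
  }
  I_H <- opsin$f_H * opsin$g_max_nS * activation * (V - opsin$E_ops_mV)  # pA
  influx <- pmin(I_H, 0)
  conv <- 1e-12 / (.FARADAY * geom$volume_L * phys$beta_buff)  # pH per pA*s
  pH + dt * (influx * conv + phys$k_rec * (phys$pH_rest - pH))
}

#' Render sensor fluorescence from a pH trace
#'
#' `F = F_max / (1 + 10^(hill_n * (pKa - pH))) + F_ref * artifact_rate * dose
#' + noise`, where `F_ref` is the Hill fluorescence at the sensor's reference
#' pH, `dose` is the cumulative blue-light exposure (J cm^-2) and the noise
#' is Gaussian with sd `noise_sd * F_ref`. Deterministic given `seed`.
#'
#' @param pH numeric pH trace (finite).
#' @param sensor a [sensor_params()] object.
#' @param protocol optional [build_protocol()]; with `t`, used to compute the
#'   blue dose at each sample.
#' @param t sample times (s), required with `protocol`.
#' @param dose cumulative blue dose (J cm^-2) per sample; overrides
#'   `protocol`. Default 0 (no photoartifact).
#' @param seed RNG seed for the noise draw (optional).
#' @return Fluorescence trace (arbitrary units).
#' @export
render_fluorescence <- function(pH, sensor, protocol = NULL, t = NULL,
                                dose = NULL, seed = NULL) {
  if (any(!is.finite(pH))) stop("pH trace must be finite", call. = FALSE)
  if (is.null(dose)) {
    dose <- if (!is.null(protocol)) {
      if (is.null(t)) stop("t is required with protocol", call. = FALSE)
      blue_dose(protocol, t)
    } else 0
  }
  F_ref <- sensor$F_max / (1 + 10^(sensor$hill_n * (sensor$pKa - sensor$pH_ref)))
  Fv <- sensor$F_max / (1 + 10^(sensor$hill_n * (sensor$pKa - pH))) +
    F_ref * sensor$artifact_rate * dose
  if (sensor$noise_sd > 0) {
    Fv <- Fv + with_seed(seed, rnorm(length(pH), 0, sensor$noise_sd * F_ref))
  }
  Fv
}

#' Simulate a single compartment under interleaved stimulation
#'
#' Jointly integrates the opsin gate, the membrane voltage and intracellular
#' pH over a stimulation/imaging protocol with a fixed-step explicit Euler
#' scheme, then renders sensor fluorescence (Hill response + cumulative
#' blue-light photoartifact + optional Gaussian noise). Bitwise reproducible
#' given `seed`.
#'
#' @param geom a [compartment_geometry()]; default a 10-um-radius soma.
#' @param opsin an [opsin_params()]; default the proton-permeable reference
#'   variant ([opsin_preset()] `"cheriff"`).
#' @param sensor a [sensor_params()].
#' @param phys a [physiology_params()].
#' @param protocol a [build_protocol()]; default the standard 150-s
#'   interleaved + 150-s recovery protocol.
#' @param seed RNG seed for the fluorescence noise.
#' @param dt integration step (s). Default: a quarter of the voltage
#'   stability bound, capped at 0.5 ms.
#' @return A `sim_trace`: data frame with columns `t`, `V_mV`, `pH`, `F`,
#'   `activation`, `epoch`, carrying all parameter sets, the seed and the
#'   step size as attributes.
#' @examples
#' \donttest{
#' tr <- simulate_cell(protocol = build_protocol(0.5, 1, 15, 15))
#' min(tr$pH)
#' }
#' @export
simulate_cell <- function(geom = compartment_geometry("sphere", 10),
                          opsin = opsin_preset("cheriff"),
                          sensor = sensor_params(),
                          phys = physiology_params(),
                          protocol = build_protocol(0.5, 1, 150, 150),
                          seed = NULL, dt = NULL) {
  bound <- 2 * phys$C_m_pF / (phys$g_leak_nS + opsin$g_max_nS) / 1000
  if (is.null(dt)) dt <- min(5e-4, bound / 4)
  if (dt > bound) {
    stop(sprintf("dt = %g s violates the stability bound 2*C_m/(g_leak + g_max) = %g s",
                 dt, bound), call. = FALSE)
  }
  total <- attr(protocol, "total_s")
  n <- max(1L, as.integer(round(total / dt)))
  t <- (0:n) * dt
  sched <- gate_schedule(opsin, protocol, t[-1] - dt / 2, dt)

  a <- numeric(n + 1); V <- numeric(n + 1); pH <- numeric(n + 1)
  V[1] <- phys$E_K_mV; pH[1] <- phys$pH_rest
  target <- sched$target; decay <- sched$decay
  gl <- phys$g_leak_nS; EK <- phys$E_K_mV
  gm <- opsin$g_max_nS; Eo <- opsin$E_ops_mV; fH <- opsin$f_H
  Cm <- phys$C_m_pF
  conv <- 1e-12 / (.FARADAY * geom$volume_L * phys$beta_buff)
  krec <- phys$k_rec; pHr <- phys$pH_rest
  av <- 0; Vv <- V[1]; pv <- pH[1]
  clipped <- 0L
  for (k in seq_len(n)) {
    av <- target[k] + (av - target[k]) * decay[k]
    Vv <- Vv + dt * 1e3 * (-gl * (Vv - EK) - gm * av * (Vv - Eo)) / Cm
    IH <- fH * gm * av * (Vv - Eo)
    if (IH > 0) IH <- 0
    pv <- pv + dt * (IH * conv + krec * (pHr - pv))
    if (pv < 4) { pv <- 4; clipped <- clipped + 1L }
    if (pv > 9) { pv <- 9; clipped <- clipped + 1L }
    a[k + 1] <- av; V[k + 1] <- Vv; pH[k + 1] <- pv
  }

  # cumulative blue dose, stepwise over the grid
  ep <- epoch_at(protocol, pmin(t[-1] - dt / 2, total - 1e-9))
  blue <- !is.na(ep) & protocol$channel[ep] == "stim" &
    !is.na(protocol$wavelength[ep]) & protocol$wavelength[ep] <= 500
  dose <- c(0, cumsum(ifelse(blue, protocol$intensity[ep] / 1000, 0) * dt))

  Fv <- render_fluorescence(pH, sensor, dose = dose, seed = seed)
  epoch_lab <- c("dark", ifelse(is.na(ep), "dark", protocol$channel[ep]))

  out <- data.frame(t = t, V_mV = V, pH = pH, F = Fv,
                    activation = a, epoch = epoch_lab,
                    stringsAsFactors = FALSE)
  structure(out,
            params = list(geom = geom, opsin = opsin, sensor = sensor,
                          phys = phys, protocol = protocol),
            seed = seed, dt = dt, clipped = clipped,
            class = c("sim_trace", "data.frame"))
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("Simulated compartment trace: ", nrow(x), " samples over ",
      max(x$t), " s (dt = ", attr(x, "dt"), " s)\n", sep = "")
  cat(sprintf("  pH %.3f -> min %.3f (final %.3f); V rest %.1f mV, min %.1f mV\n",
              x$pH[1], min(x$pH), x$pH[nrow(x)], x$V_mV[1], min(x$V_mV)))
  if (attr(x, "clipped") > 0) {
    cat("  note:", attr(x, "clipped"), "samples clipped to the pH (4, 9) range\n")
  }
  invisible(x)
}

#' @export
plot.sim_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$V_mV, type = "l", xlab = "", ylab = "V (mV)", ...)
  graphics::plot(x$t, x$pH, type = "l", xlab = "", ylab = "pH", ...)
  graphics::plot(x$t, x$F, type = "l", xlab = "time (s)",
                 ylab = "F (a.u.)", ...)
  invisible(x)
}
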