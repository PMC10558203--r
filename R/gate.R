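#' Opsin activation gate
#'
#' First-order gating model of a channelrhodopsin. During illumination the
#' activation relaxes toward the peak steady state
#' `a_peak = s(lambda) * P / (P + EPD50)` with intensity-dependent time
#' constant `tau_on(P) = tau_on_sat * (1 + EPD50/P)`; once the rise is
#' essentially complete (5 opening time constants after light onset) the
#' target steps down multiplicatively to `desensitization_ratio * a_peak`
#' (a single step, no second kinetic state). After light-off the gate closes
#' as a single exponential with `tau_off`.
#'
#' @param opsin an [opsin_params()] object.
#' @param intensity light power density (mW cm^-2, >= 0).
#' @param wavelength stimulation wavelength (nm); must be present in the
#'   opsin's spectrum (unknown wavelengths error rather than silently
#'   contributing zero).
#' @param t time grid (s, strictly increasing, starting at light onset).
#' @param light logical vector over `t`: TRUE while the light is on
#'   (default: on for the whole grid).
#' @param a0 initial activation in \[0, 1\].
#' @return Numeric activation trace in \[0, 1\] over `t`.
#' @examples
#' op <- opsin_params(10, 0, 0.5, EPD50_mW_cm2 = 22, tau_on_sat_ms = 5,
#'                    tau_off_ms = 16)
#' a <- opsin_gate(op, intensity = 22, wavelength = 488, t = seq(0, 0.2, 1e-3))
#' tail(a, 1)  # ~ 0.5 * desensitization_ratio
#' @export
opsin_gate <- function(opsin, intensity, wavelength, t,
                       light = rep(TRUE, length(t)), a0 = 0) {
  stopifnot(inherits(opsin, "opsin_params"))
  if (!is.finite(intensity) || intensity < 0) {
    stop("intensity must be >= 0", call. = FALSE)
  }
  if (length(t) == 0) return(numeric(0))
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  s <- spectrum_at(opsin, wavelength)
  light <- light & intensity > 0

  a <- numeric(length(t))
  runs <- rle(light)
  idx_end <- cumsum(runs$lengths)
  idx_start <- c(1, head(idx_end, -1) + 1)
  a_cur <- a0
  for (r in seq_along(runs$values)) {
    ii <- idx_start[r]:idx_end[r]
    t0 <- if (idx_start[r] == 1) t[1] else t[idx_start[r] - 1]
    tr <- t[ii] - t0
    if (runs$values[r]) {
      P <- intensity
      a_peak <- s * P / (P + opsin$EPD50_mW_cm2)
      tau_on <- opsin$tau_on_sat_ms * (1 + opsin$EPD50_mW_cm2 / P) / 1000
      t_step <- 5 * tau_on  # rise >99% complete; desensitization steps in
      R <- opsin$desensitization_ratio
      pre <- tr < t_step
      a[ii[pre]] <- a_peak + (a_cur - a_peak) * exp(-tr[pre] / tau_on)
      if (any(!pre)) {
        a_at_step <- a_peak + (a_cur - a_peak) * exp(-t_step / tau_on)
        a_ss <- R * a_peak
        a[ii[!pre]] <- a_ss + (a_at_step - a_ss) *
          exp(-(tr[!pre] - t_step) / tau_on)
      }
    } else {
      tau_off <- opsin$tau_off_ms / 1000
      a[ii] <- a_cur * exp(-tr / tau_off)
    }
    a_cur <- a[idx_end[r]]
  }
  a
}

# Per-step gate drive over a simulation grid: for each step, the first-order
# target and decay factor exp(-dt/tau) implied by the protocol epoch the step
# falls in. Used by the compartment and monolayer integrators.
gate_schedule <- function(opsin, protocol, t, dt) {
  ep <- epoch_at(protocol, pmin(t, attr(protocol, "total_s") - 1e-9))
  ch <- protocol$channel[ep]
  wl <- protocol$wavelength[ep]
  P <- protocol$intensity[ep]
  target <- numeric(length(t))
  tau <- rep(opsin$tau_off_ms / 1000, length(t))
  lit <- !is.na(wl) & P > 0
  if (any(lit)) {
    s <- vapply(unique(wl[lit]), function(w) spectrum_at(opsin, w), numeric(1))
    names(s) <- as.character(unique(wl[lit]))
    svec <- s[as.character(wl[lit])]
    a_peak <- svec * P[lit] / (P[lit] + opsin$EPD50_mW_cm2)
    tau_on <- opsin$tau_on_sat_ms * (1 + opsin$EPD50_mW_cm2 / P[lit]) / 1000
    # single multiplicative desensitization step 5*tau_on into each epoch
    t_in <- t[lit] - protocol$t_start[ep[lit]]
    R <- ifelse(t_in < 5 * tau_on, 1, opsin$desensitization_ratio)
    target[lit] <- R * a_peak
    tau[lit] <- tau_on
  }
  list(target = target, decay = exp(-dt / tau), channel = ch,
       stim = !is.na(ch) & ch == "stim")
}
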