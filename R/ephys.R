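#' Photocurrent recording container
#'
#' @param t_ms time (ms), strictly increasing.
#' @param I_pA current (pA).
#' @param segments data frame of stimulus segments with columns `t_on_ms`,
#'   `t_off_ms`, `wavelength`, `intensity` (must lie within the record span).
#' @param V_hold_mV holding voltage (mV).
#' @return A `photocurrent_recording`.
#' @export
photocurrent_recording <- function(t_ms, I_pA, segments = NULL,
                                   V_hold_mV = -70) {
  if (any(diff(t_ms) <= 0)) stop("t_ms must be strictly increasing",
                                 call. = FALSE)
  if (length(t_ms) != length(I_pA)) stop("t and I length mismatch",
                                         call. = FALSE)
  if (!is.null(segments)) {
    if (any(segments$t_on_ms < min(t_ms) - 1e-9) ||
        any(segments$t_off_ms > max(t_ms) + 1e-9)) {
      stop("stimulus segments outside the record span", call. = FALSE)
    }
  }
  structure(list(t_ms = t_ms, I_pA = I_pA, segments = segments,
                 V_hold_mV = V_hold_mV),
            class = "photocurrent_recording")
}

#' Simulate a voltage-clamp photocurrent recording
#'
#' Generates `I = g_max * a(t) * (V_hold - E_ops)` with the opsin gate of
#' [opsin_gate()] (intensity-dependent opening, single desensitization step,
#' exponential closing) plus optional Gaussian noise. Deterministic given
#' `seed`.
#'
#' @param opsin an [opsin_params()].
#' @param intensity,wavelength stimulus light (mW cm^-2, nm).
#' @param t_on_ms,t_off_ms light-on interval (ms).
#' @param t_total_ms record length (ms).
#' @param dt_ms sample interval (ms).
#' @param V_hold_mV holding voltage (mV).
#' @param noise_sd_pA Gaussian current noise (pA).
#' @param seed RNG seed.
#' @return A [photocurrent_recording()].
#' @export
simulate_photocurrent <- function(opsin, intensity, wavelength = 488,
                                  t_on_ms = 50, t_off_ms = 550,
                                  t_total_ms = 1000, dt_ms = 0.5,
                                  V_hold_mV = -70, noise_sd_pA = 0,
                                  seed = NULL) {
  t_ms <- (0:ceiling(t_total_ms / dt_ms)) * dt_ms
  light <- t_ms >= t_on_ms & t_ms < t_off_ms
  a <- opsin_gate(opsin, intensity, wavelength, t_ms / 1000, light = light)
  I <- opsin$g_max_nS * a * (V_hold_mV - opsin$E_ops_mV)
  if (noise_sd_pA > 0) {
    I <- I + with_seed(seed, rnorm(length(I), 0, noise_sd_pA))
  }
  photocurrent_recording(
    t_ms, I,
    segments = data.frame(t_on_ms = t_on_ms, t_off_ms = t_off_ms,
                          wavelength = wavelength, intensity = intensity),
    V_hold_mV = V_hold_mV)
}

#' Centered moving-average smoothing
#'
#' Noise reduction for current traces: a centered moving average of odd
#' window width, with the window shrinking symmetrically at the edges (so a
#' window of 1 is the identity and a constant trace is unchanged).
#'
#' @param I numeric trace.
#' @param window odd integer >= 1, at most the trace length.
#' @return Smoothed trace of the same length.
#' @export
smooth_trace <- function(I, window = 5) {
  if (window %% 2 != 1 || window < 1) {
    stop("window must be an odd integer >= 1", call. = FALSE)
  }
  n <- length(I)
  if (window > n) stop("window larger than trace", call. = FALSE)
  if (window == 1) return(I)
  half <- (window - 1) / 2
  cs <- cumsum(c(0, I))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  # shrink symmetrically at the edges to keep the average centered
  shrink <- pmin(seq_len(n) - lo, hi - seq_len(n))
  lo <- seq_len(n) - shrink
  hi <- seq_len(n) + shrink
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Peak and steady-state photocurrent
#'
#' `I_peak` is the extremal current after light onset; `I_ss` is the mean of
#' the last 20% of the light window. The reported `ratio` is `I_ss/I_peak`
#' (1.00 for a sag-free response; this is the quantity conventionally
#' tabulated for opsin desensitization even when the column is headed
#' peak/steady-state).
#'
#' @param rec a [photocurrent_recording()].
#' @param light_window length-2 numeric (ms) covering at least 50 samples.
#' @param floor_pA currents below this magnitude count as no photocurrent.
#' @return List with `I_peak`, `I_ss` (pA) and `ratio`.
#' @export
peak_steady <- function(rec, light_window = NULL, floor_pA = 1e-6) {
  if (is.null(light_window)) {
    light_window <- c(rec$segments$t_on_ms[1], rec$segments$t_off_ms[1])
  }
  sel <- which(rec$t_ms >= light_window[1] & rec$t_ms <= light_window[2])
  if (length(sel) < 50) {
    stop("light window too short: need >= 50 samples, got ", length(sel),
         call. = FALSE)
  }
  I <- rec$I_pA[sel]
  I_peak <- I[which.max(abs(I))]
  if (abs(I_peak) <= floor_pA) stop("no photocurrent detected", call. = FALSE)
  tail_sel <- tail(sel, max(1, ceiling(0.2 * length(sel))))
  I_ss <- mean(rec$I_pA[tail_sel])
  list(I_peak = I_peak, I_ss = I_ss, ratio = I_ss / I_peak)
}

#' Fit a single-exponential gating time constant
#'
#' Fits `I(t) = A * exp(-(t - t0)/tau) + C` by least squares on the smoothed
#' trace over the opening (`phase = "on"`, from light onset) or closing
#' (`phase = "off"`, from light offset) window. The fit is flagged as a
#' likely model misfit (e.g. bi-exponential kinetics) when its residual RMSE
#' exceeds `flag_k` times a robust estimate of the recording noise (from the
#' median absolute first difference of the raw trace), so noise alone never
#' triggers the flag.
#'
#' @param rec a [photocurrent_recording()].
#' @param phase `"on"` or `"off"`.
#' @param window optional length-2 window (ms); defaults to the relevant
#'   stimulus phase.
#' @param smooth_window moving-average width applied before fitting.
#' @param flag_k misfit flag threshold, in units of the estimated noise sd.
#' @return List with `tau_ms`, `rmse`, `rel_rmse` (RMSE over response
#'   amplitude), `sigma_est`, `flagged`, `converged`; non-convergence yields
#'   `tau_ms = NULL` with diagnostics in `reason`.
#' @export
fit_tau <- function(rec, phase = c("on", "off"), window = NULL,
                    smooth_window = 5, flag_k = 5) {
  phase <- match.arg(phase)
  seg <- rec$segments[1, ]
  if (is.null(window)) {
    window <- if (phase == "on") c(seg$t_on_ms, seg$t_off_ms)
              else c(seg$t_off_ms, max(rec$t_ms))
  }
  sel <- rec$t_ms >= window[1] & rec$t_ms <= window[2]
  if (sum(sel) < 10) stop("phase window must contain >= 10 samples",
                          call. = FALSE)
  tt <- rec$t_ms[sel]
  y <- smooth_trace(rec$I_pA, min(smooth_window,
                                  2 * floor((sum(sel) - 1) / 2) + 1))[sel]
  t0 <- tt[1]
  C0 <- if (phase == "on") mean(tail(y, max(2, ceiling(0.1 * length(y))))) else 0
  A0 <- y[1] - C0
  resid0 <- y - C0
  pos <- which(sign(resid0) == sign(A0 + 1e-15) &
                 abs(resid0) > 1e-3 * max(abs(resid0)))
  tau0 <- if (length(pos) >= 3) {
    sl <- unname(coef(stats::lm(log(abs(resid0[pos])) ~ tt[pos]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(tt)) / 3
  } else diff(range(tt)) / 3
  # a second, perturbed start guards against the rank-deficient Jacobian that
  # an (almost) exact-fit start produces on noiseless data
  fit <- NULL
  for (st in list(list(A = A0, C = C0, tau = tau0),
                  list(A = 0.9 * A0, C = C0, tau = 1.25 * tau0))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(tt - t0) / tau) + C, start = st,
                        lower = c(-Inf, -Inf, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    return(list(tau_ms = NULL, converged = FALSE,
                reason = paste("non-convergence:", conditionMessage(fit))))
  }
  cf <- coef(fit)
  amp <- max(abs(y - cf[["C"]]))
  rmse <- sqrt(mean(resid(fit)^2))
  rel <- if (amp > 0) rmse / amp else 0
  # robust noise level from raw first differences (MAD-consistent)
  raw <- rec$I_pA[sel]
  sigma_est <- stats::median(abs(diff(raw))) * 1.4826 / sqrt(2)
  list(tau_ms = unname(cf[["tau"]]), rmse = rmse, rel_rmse = rel,
       sigma_est = sigma_est,
       flagged = rmse > flag_k * (sigma_est + 1e-12), converged = TRUE)
}

#' Fit the light-sensitivity curve (EPD50)
#'
#' Least-squares fit of the saturation law
#' `I_ss(P) = I_max * P / (P + EPD50)` to steady-state photocurrent versus
#' power density; the EPD50 is the power density giving half-maximal
#' current. Optional seeded bootstrap over points for a confidence interval.
#'
#' @param series data frame with columns `intensity` (mW cm^-2) and `I_ss`
#'   (pA; magnitudes are used).
#' @param n_boot bootstrap resamples (0 = none).
#' @param seed bootstrap RNG seed.
#' @return List with `EPD50`, `I_max`, optional `ci` (2.5/97.5% bootstrap
#'   quantiles), and `span_warning`.
#' @export
fit_epd50 <- function(series, n_boot = 0, seed = NULL) {
  stopifnot(all(c("intensity", "I_ss") %in% names(series)))
  if (nrow(series) < 4) stop("need >= 4 intensities", call. = FALSE)
  P <- series$intensity; I <- abs(series$I_ss)
  span_warning <- FALSE
  if (max(P) / max(min(P[P > 0]), 1e-12) < 10) {
    warning("intensities span less than one decade; EPD50 poorly identified",
            call. = FALSE)
    span_warning <- TRUE
  }
  do_fit <- function(P, I) {
    K0 <- P[which.min(abs(I - max(I) / 2))]
    starts <- list(list(Imax = max(I), K = max(K0, 1e-6)),
                   list(Imax = 1.2 * max(I), K = stats::median(P)))
    for (st in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(I ~ Imax * P / (P + K), start = st,
                          lower = c(1e-12, 1e-12),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) return(coef(fit))
    }
    stop("saturation fit failed to converge", call. = FALSE)
  }
  cf <- do_fit(P, I)
  out <- list(EPD50 = unname(cf[["K"]]), I_max = unname(cf[["Imax"]]),
              span_warning = span_warning)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample(length(P), replace = TRUE)
        tryCatch(do_fit(P[idx], I[idx])[["K"]], error = function(e) NA_real_)
      }, numeric(1))
    })
    out$ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  out
}

#' Reversal potential from an I-V series
#'
#' Linear interpolation between the two holding voltages bracketing the zero
#' crossing of the steady-state current. With multiple crossings the one
#' nearest 0 mV is returned, flagged; with no sign change extrapolation is
#' refused.
#'
#' @param iv data frame with columns `V` (mV) and `I` (pA).
#' @return List with `Vr_mV` (or `NULL` with `reason`), `multiple_crossings`.
#' @export
reversal_potential <- function(iv) {
  iv <- iv[order(iv$V), , drop = FALSE]
  V <- iv$V; I <- iv$I
  cross <- which(I[-length(I)] * I[-1] < 0)
  exact0 <- which(I == 0)
  vr <- c(V[exact0],
          vapply(cross, function(k) {
            V[k] - I[k] * (V[k + 1] - V[k]) / (I[k + 1] - I[k])
          }, numeric(1)))
  if (length(vr) == 0) {
    return(list(Vr_mV = NULL, reason = "extrapolation refused: no sign change",
                multiple_crossings = FALSE))
  }
  list(Vr_mV = vr[which.min(abs(vr))], reason = NULL,
       multiple_crossings = length(vr) > 1)
}

#' Ideal Nernstian reversal-potential shift
#'
#' Predicted shift of the reversal potential when the extracellular
#' concentration of a perfectly selective permeant ion changes:
#' `dVr = (RT/zF) * ln(c_after / c_before)`. The ratio of a measured shift
#' to this prediction is a selectivity index for that ion (0 for an ion the
#' channel does not conduct).
#'
#' @param c_out_before,c_out_after extracellular concentrations (mM, > 0).
#' @param ion_valence ion charge z.
#' @param temperature_K temperature (K).
#' @return Shift in mV (antisymmetric under swapping before/after).
#' @examples
#' nernst_shift(120, 1, 1, 298)  # -122.9 mV
#' @export
nernst_shift <- function(c_out_before, c_out_after, ion_valence = 1,
                         temperature_K = 298.15) {
  if (c_out_before <= 0 || c_out_after <= 0) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  1000 * .RGAS * temperature_K / (ion_valence * .FARADAY) *
    log(c_out_after / c_out_before)
}

#' Action spectrum normalized to the blue reference
#'
#' Per-wavelength steady-state photocurrents divided by the 488-nm current;
#' values below the detection floor are censored and reported as
#' `"< floor"`.
#'
#' @param currents named numeric vector of `I_ss` by wavelength (names in
#'   nm), or a data frame with `wavelength` and `I_ss`.
#' @param reference_nm the normalizing wavelength (must be present with
#'   nonzero current).
#' @param floor relative detection floor (default 0.003 of the reference).
#' @return Data frame with `wavelength`, `relative`, `censored`, `display`.
#' @export
action_spectrum <- function(currents, reference_nm = 488, floor = 0.003) {
  if (is.data.frame(currents)) {
    wl <- currents$wavelength; I <- currents$I_ss
  } else {
    wl <- as.numeric(names(currents)); I <- unname(currents)
  }
  ref <- which(wl == reference_nm)
  if (length(ref) != 1 || abs(I[ref]) == 0) {
    stop("reference wavelength ", reference_nm,
         " nm missing or has zero current", call. = FALSE)
  }
  rel <- abs(I) / abs(I[ref])
  censored <- rel < floor
  data.frame(wavelength = wl, relative = ifelse(censored, NA_real_, rel),
             censored = censored,
             display = ifelse(censored, paste0("< ", floor),
                              formatC(rel, digits = 3, format = "fg")),
             stringsAsFactors = FALSE)
}

#' Imaging-light crosstalk fractions
#'
#' Quantifies how red-shifted imaging light perturbs an opsin: the
#' activating crosstalk is `I_red_only / I_blue`; the inactivating crosstalk
#' is `1 - I_combo / I_blue` (combined blue + red versus blue alone).
#'
#' @param I_blue photocurrent under blue light alone (reference, > floor).
#' @param I_combo photocurrent under blue + red-shifted light.
#' @param I_red_only photocurrent under the red-shifted light alone.
#' @param floor detection floor for the blue reference.
#' @return List with `activation_fraction` and `inactivation_fraction`.
#' @export
crosstalk <- function(I_blue, I_combo, I_red_only, floor = 1e-9) {
  if (abs(I_blue) <= floor) {
    stop("blue reference current at or below the detection floor",
         call. = FALSE)
  }
  list(activation_fraction = I_red_only / I_blue,
       inactivation_fraction = 1 - I_combo / I_blue)
}

#' Characterize an opsin from synthetic voltage-clamp recordings
#'
#' Runs the full gating characterization on recordings simulated from a
#' known parameter set: intensity series for the EPD50, opening and closing
#' time-constant fits at saturating light, opening at the EPD50, an I-V
#' series for the reversal potential, and the peak/steady-state ratio. Used
#' for self-consistency validation of the fitting chain.
#'
#' @param opsin an [opsin_params()].
#' @param intensities intensity series (mW cm^-2) for the sensitivity fit.
#' @param V_levels holding voltages (mV) for the I-V series.
#' @param noise_sd_pA recording noise (pA).
#' @param seed RNG seed.
#' @return A `characterization_result`: list with `Vr_mV`,
#'   `tau_on_fastest_ms`, `tau_on_at_EPD50_ms`, `tau_off_ms`,
#'   `EPD50_mW_cm2`, `I_ss_pA`, `peak_ratio` (steady-state/peak).
#' @export
characterize_opsin <- function(opsin,
                               intensities = c(2, 5, 10, 20, 50, 100, 200,
                                               500, 1000, 2000),
                               V_levels = seq(-70, 40, by = 10),
                               noise_sd_pA = 0, seed = NULL) {
  sat <- 100 * opsin$EPD50_mW_cm2
  tau_scale <- max(opsin$tau_on_sat_ms, opsin$tau_off_ms)
  t_on <- 20; t_light <- max(200, 12 * opsin$tau_on_sat_ms)
  t_dark <- max(300, 8 * opsin$tau_off_ms)

  rec_sat <- simulate_photocurrent(
    opsin, sat, 488, t_on_ms = t_on, t_off_ms = t_on + t_light,
    t_total_ms = t_on + t_light + t_dark,
    dt_ms = max(0.05, tau_scale / 400),
    noise_sd_pA = noise_sd_pA, seed = seed)
  on_fit <- fit_tau(rec_sat, "on",
                    window = c(t_on, t_on + 3 * opsin$tau_on_sat_ms))
  off_fit <- fit_tau(rec_sat, "off")
  ps <- peak_steady(rec_sat)

  rec_ep <- simulate_photocurrent(
    opsin, opsin$EPD50_mW_cm2, 488, t_on_ms = t_on,
    t_off_ms = t_on + 24 * opsin$tau_on_sat_ms,
    t_total_ms = t_on + 24 * opsin$tau_on_sat_ms + 50,
    dt_ms = max(0.05, opsin$tau_on_sat_ms / 100),
    noise_sd_pA = noise_sd_pA,
    seed = if (is.null(seed)) NULL else seed + 1)
  on_ep <- fit_tau(rec_ep, "on",
                   window = c(t_on, t_on + 6 * opsin$tau_on_sat_ms))

  iss <- vapply(seq_along(intensities), function(i) {
    r <- simulate_photocurrent(
      opsin, intensities[i], 488, t_on_ms = 0,
      t_off_ms = t_light + 20 * opsin$tau_on_sat_ms,
      t_total_ms = t_light + 20 * opsin$tau_on_sat_ms,
      dt_ms = max(0.1, tau_scale / 200), noise_sd_pA = noise_sd_pA,
      seed = if (is.null(seed)) NULL else seed + 10 + i)
    peak_steady(r, c(0, max(r$t_ms)))$I_ss
  }, numeric(1))
  ep_fit <- fit_epd50(data.frame(intensity = intensities, I_ss = iss))

  ivI <- vapply(seq_along(V_levels), function(i) {
    r <- simulate_photocurrent(
      opsin, sat, 488, t_on_ms = 0, t_off_ms = 200, t_total_ms = 200,
      dt_ms = 0.5, V_hold_mV = V_levels[i], noise_sd_pA = noise_sd_pA,
      seed = if (is.null(seed)) NULL else seed + 100 + i)
    peak_steady(r, c(0, 200), floor_pA = 0)$I_ss
  }, numeric(1))
  ok <- abs(ivI) > 0 | TRUE
  vr <- reversal_potential(data.frame(V = V_levels[ok], I = ivI[ok]))

  structure(list(Vr_mV = vr$Vr_mV,
                 tau_on_fastest_ms = on_fit$tau_ms,
                 tau_on_at_EPD50_ms = on_ep$tau_ms,
                 tau_off_ms = off_fit$tau_ms,
                 EPD50_mW_cm2 = ep_fit$EPD50,
                 I_ss_pA = ps$I_ss,
                 peak_ratio = ps$ratio),
            class = "characterization_result")
}

#' @export
print.characterization_result <- function(x, ...) {
  cat("Opsin gating characterization\n")
  fmt <- function(v) if (is.null(v)) "NA" else formatC(v, digits = 4,
                                                       format = "g")
  cat("  Reversal potential:   ", fmt(x$Vr_mV), "mV\n")
  cat("  tau_on (saturating):  ", fmt(x$tau_on_fastest_ms), "ms\n")
  cat("  tau_on (at EPD50):    ", fmt(x$tau_on_at_EPD50_ms), "ms\n")
  cat("  tau_off:              ", fmt(x$tau_off_ms), "ms\n")
  cat("  EPD50:                ", fmt(x$EPD50_mW_cm2), "mW cm^-2\n")
  cat("  Steady-state current: ", fmt(x$I_ss_pA), "pA\n")
  cat("  steady/peak ratio:    ", fmt(x$peak_ratio), "\n")
  invisible(x)
}
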