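#' Compartment geometry
#'
#' Well-mixed compartment shapes used by the simulator. The surface-to-volume
#' ratio sets how fast a given membrane proton flux changes intracellular
#' concentration: 3/r for a sphere, 2/r for a cylinder (end caps ignored).
#'
#' @param shape `"sphere"` (soma-like) or `"cylinder"` (dendrite-like).
#' @param radius_um radius in micrometres (> 0).
#' @param length_um cylinder length in micrometres (required for cylinders).
#' @return A `compartment_geometry` with derived `area_um2`, `volume_um3`,
#'   `volume_L` and `surface_to_volume` (um^-1).
#' @examples
#' compartment_geometry("sphere", 10)$surface_to_volume    # 0.3
#' compartment_geometry("cylinder", 1, 40)$surface_to_volume  # 2
#' @export
compartment_geometry <- function(shape = c("sphere", "cylinder"),
                                 radius_um, length_um = NULL) {
  shape <- match.arg(shape)
  if (!is.finite(radius_um) || radius_um <= 0) {
    stop("radius_um must be > 0", call. = FALSE)
  }
  if (shape == "sphere") {
    area <- 4 * pi * radius_um^2
    vol <- 4 / 3 * pi * radius_um^3
    s2v <- 3 / radius_um
  } else {
    if (is.null(length_um) || !is.finite(length_um) || length_um <= 0) {
      stop("cylinder requires length_um > 0", call. = FALSE)
    }
    area <- 2 * pi * radius_um * length_um      # lateral surface only
    vol <- pi * radius_um^2 * length_um
    s2v <- 2 / radius_um
  }
  stopifnot(abs(area / vol - s2v) < 1e-9 * s2v)  # closed-form consistency
  structure(list(shape = shape, radius_um = radius_um,
                 length_um = if (shape == "cylinder") length_um else NA_real_,
                 area_um2 = area, volume_um3 = vol,
                 volume_L = vol * 1e-15,
                 surface_to_volume = s2v),
            class = "compartment_geometry")
}

#' Opsin (channelrhodopsin) parameters
#'
#' Lumped description of a light-gated cation channel. `f_H` is the
#' phenomenological fraction of the photocurrent carried by protons (not a
#' GHK permeability); proton-impermeable variants have `f_H = 0`. The
#' opening time constant is intensity dependent,
#' `tau_on(P) = tau_on_sat_ms * (1 + EPD50/P)`, so it equals `tau_on_sat_ms`
#' at saturating light.
#'
#' @param g_max_nS maximal conductance (nS).
#' @param E_ops_mV reversal potential (mV).
#' @param f_H fraction of current carried by protons, in \[0, 1\].
#' @param EPD50_mW_cm2 effective power density for 50% activation (mW cm^-2).
#' @param tau_on_sat_ms opening time constant at saturating light (ms).
#' @param tau_off_ms closing time constant after light off (ms).
#' @param desensitization_ratio steady-state/peak current ratio in (0, 1].
#' @param spectrum named numeric vector of relative sensitivity by wavelength
#'   (nm); must contain the 488-nm reference with value 1.
#' @return An `opsin_params` object.
#' @seealso [opsin_preset()] for ready-made variants.
#' @export
opsin_params <- function(g_max_nS, E_ops_mV, f_H, EPD50_mW_cm2,
                         tau_on_sat_ms, tau_off_ms,
                         desensitization_ratio = 1,
                         spectrum = c("488" = 1)) {
  pos <- c(g_max_nS = g_max_nS, EPD50_mW_cm2 = EPD50_mW_cm2,
           tau_on_sat_ms = tau_on_sat_ms, tau_off_ms = tau_off_ms)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("opsin parameters must be positive: ",
         paste(names(pos)[!is.finite(pos) | pos <= 0], collapse = ", "),
         call. = FALSE)
  }
  if (!is.finite(f_H) || f_H < 0 || f_H > 1) {
    stop("f_H must be in [0, 1]", call. = FALSE)
  }
  if (desensitization_ratio <= 0 || desensitization_ratio > 1) {
    stop("desensitization_ratio must be in (0, 1]", call. = FALSE)
  }
  spectrum <- unlist(spectrum)
  if (is.null(names(spectrum)) || !"488" %in% names(spectrum)) {
    stop("spectrum must include the 488 nm reference wavelength",
         call. = FALSE)
  }
  if (abs(spectrum[["488"]] - 1) > 1e-12) {
    stop("spectrum at the 488 nm reference must equal 1", call. = FALSE)
  }
  if (any(spectrum < 0 | spectrum > 1)) {
    stop("spectrum values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(g_max_nS = g_max_nS, E_ops_mV = E_ops_mV, f_H = f_H,
                 EPD50_mW_cm2 = EPD50_mW_cm2, tau_on_sat_ms = tau_on_sat_ms,
                 tau_off_ms = tau_off_ms,
                 desensitization_ratio = desensitization_ratio,
                 spectrum = spectrum),
            class = "opsin_params")
}

#' Preset opsin parameter sets
#'
#' Ready-made parameter sets for the three channelrhodopsin variants the
#' package models. Gating numbers (EPD50, time constants, reversal potential,
#' desensitization, relative spectral sensitivity) follow published
#' whole-cell characterization of each variant; `g_max` is set so the
#' saturating steady-state photocurrent at -70 mV matches the reported
#' amplitude scale; `f_H` is 0.5 for the proton-permeable reference variant
#' and 0 for the engineered low-proton-permeability variants.
#'
#' @param name one of `"cheriff"`, `"chr2_3m"`, `"pscatch2"`.
#' @return An [opsin_params()] object.
#' @export
opsin_preset <- function(name = c("cheriff", "chr2_3m", "pscatch2")) {
  name <- match.arg(name)
  switch(name,
    cheriff = opsin_params(
      g_max_nS = 20, E_ops_mV = 4, f_H = 0.5, EPD50_mW_cm2 = 22,
      tau_on_sat_ms = 4.5, tau_off_ms = 16, desensitization_ratio = 0.65,
      spectrum = c("488" = 1, "532" = 0.7, "561" = 0, "594" = 0,
                   "640" = 0)),
    chr2_3m = opsin_params(
      g_max_nS = 19, E_ops_mV = 16.6, f_H = 0, EPD50_mW_cm2 = 11.6,
      tau_on_sat_ms = 57, tau_off_ms = 1950, desensitization_ratio = 1,
      spectrum = c("488" = 1, "532" = 0.6, "561" = 0.20, "594" = 0.048,
                   "640" = 0)),
    pscatch2 = opsin_params(
      g_max_nS = 11, E_ops_mV = 12.3, f_H = 0, EPD50_mW_cm2 = 116,
      tau_on_sat_ms = 4.2, tau_off_ms = 17.6, desensitization_ratio = 0.92,
      spectrum = c("488" = 1, "532" = 0.4, "561" = 0.02, "594" = 0,
                   "640" = 0))
  )
}

#' pH-sensor parameters
#'
#' Fluorescent pH indicator model: protonation follows a Hill curve
#' `F = F_max / (1 + 10^(hill_n * (pKa - pH)))` (brighter at higher pH,
#' pKa 7.5 by default), plus a blue-light photoactivation artifact that
#' accumulates linearly with cumulative blue dose, plus Gaussian noise.
#' The default `artifact_rate` is calibrated so an opsin-negative control
#' under the standard 150-s interleaved protocol at 500 mW cm^-2 shows a
#' +0.11 delta-F/F rise.
#'
#' @param pKa sensor pKa (pH units, in (4, 10)).
#' @param hill_n Hill coefficient (> 0).
#' @param F_max maximal (fully deprotonated) fluorescence, arbitrary units.
#' @param artifact_rate photoartifact in delta-F/F (relative to baseline
#'   fluorescence at `pH_ref`) per J cm^-2 of blue exposure.
#' @param noise_sd Gaussian noise, delta-F/F units.
#' @param pH_ref reference pH anchoring delta-F/F (default 7.3).
#' @return A `sensor_params` object.
#' @export
sensor_params <- function(pKa = 7.5, hill_n = 1, F_max = 1000,
                          artifact_rate = 0.0044, noise_sd = 0,
                          pH_ref = 7.3) {
  if (!is.finite(pKa) || pKa <= 4 || pKa >= 10) {
    stop("pKa must lie in (4, 10)", call. = FALSE)
  }
  if (!is.finite(hill_n) || hill_n <= 0) stop("hill_n must be > 0", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.finite(F_max) || F_max <= 0) stop("F_max must be > 0", call. = FALSE)
  structure(list(pKa = pKa, hill_n = hill_n, F_max = F_max,
                 artifact_rate = artifact_rate, noise_sd = noise_sd,
                 pH_ref = pH_ref),
            class = "sensor_params")
}

#' Compartment physiology parameters
#'
#' Passive membrane and cytosolic proton-handling parameters. Buffering
#' capacity `beta_buff` is the moles of acid per litre needed to shift pH by
#' one unit (default 20 mmol L^-1 pH^-1, a typical cytosolic value). Proton
#' extrusion (exchanger activity) is modelled as first-order relaxation to
#' `pH_rest` at rate `k_rec`; the default gives a recovery half-time well
#' above the 150-s observation window, matching the slow, incomplete
#' recovery seen experimentally.
#'
#' @param C_m_pF membrane capacitance (pF, > 0).
#' @param g_leak_nS leak conductance (nS); with a potassium-dominated leak
#'   the resting potential sits at `E_K_mV`.
#' @param E_K_mV potassium reversal potential (mV, default -70).
#' @param beta_buff buffering capacity (mol L^-1 per pH unit, > 0).
#' @param k_rec proton-extrusion rate constant (s^-1, >= 0).
#' @param pH_rest resting pH (default 7.3).
#' @param temperature_K temperature (K).
#' @return A `physiology_params` object (the Faraday constant is fixed).
#' @export
physiology_params <- function(C_m_pF = 20, g_leak_nS = 3, E_K_mV = -70,
                              beta_buff = 0.020, k_rec = 0.003,
                              pH_rest = 7.3, temperature_K = 298.15) {
  if (!is.finite(C_m_pF) || C_m_pF <= 0) stop("C_m_pF must be > 0", call. = FALSE)
  if (!is.finite(beta_buff) || beta_buff <= 0) {
    stop("beta_buff must be > 0 (non-physical buffering capacity)",
         call. = FALSE)
  }
  if (!is.finite(k_rec) || k_rec < 0) stop("k_rec must be >= 0", call. = FALSE)
  if (!is.finite(g_leak_nS) || g_leak_nS < 0) {
    stop("g_leak_nS must be >= 0", call. = FALSE)
  }
  structure(list(C_m_pF = C_m_pF, g_leak_nS = g_leak_nS, E_K_mV = E_K_mV,
                 beta_buff = beta_buff, k_rec = k_rec, pH_rest = pH_rest,
                 temperature_K = temperature_K, faraday = .FARADAY),
            class = "physiology_params")
}

# spectral sensitivity lookup; errors on unknown wavelengths (no silent zero)
spectrum_at <- function(opsin, wavelength) {
  key <- as.character(wavelength)
  if (!key %in% names(opsin$spectrum)) {
    stop("wavelength ", wavelength,
         " nm absent from opsin spectrum (known: ",
         paste(names(opsin$spectrum), collapse = ", "), " nm)", call. = FALSE)
  }
  unname(opsin$spectrum[[key]])
}

# seed handling: set the RNG deterministically, restoring caller state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
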