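---
title: "Models and methods behind photoacid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photoacid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoacid)
```

## The problem

Channelrhodopsins are light-gated cation channels, and most of them conduct
protons. A polarized cell sits ~70 mV below its surroundings while the
extracellular proton concentration at pH 7.3 is close to the cytosolic one,
so the electrochemical driving force on protons is strongly inward. Opening
a proton-permeable channel therefore acidifies the cytosol, at a rate set by
the proton fraction of the photocurrent, the compartment's
surface-to-volume ratio, the cytosolic buffering capacity, and the stimulus
duty cycle. `photoacid` implements the full measurement chain for this
phenomenon — a mechanistic forward simulator, a fluorescence-imaging
analysis pipeline, a gap-junction monolayer simulator for patterned
stimulation, and voltage-clamp photocurrent characterization — so that every
analysis stage can be validated against synthetic data with known ground
truth.

## The compartment model

A compartment (soma or dendrite) is treated as a single well-mixed volume
with three coupled state variables.

**Opsin gate.** Activation relaxes first-order toward the light-dependent
target $a_\infty = s(\lambda)\,P/(P + \mathrm{EPD50})$, where $s(\lambda)$
is the relative spectral sensitivity (1 at the 488-nm reference) and
$\mathrm{EPD50}$ is the power density giving half activation. The opening
time constant is intensity dependent,
$\tau_\mathrm{on}(P) = \tau_\mathrm{on,sat}(1 + \mathrm{EPD50}/P)$, chosen
so that it equals the measured saturating value at high intensity and slows
at low intensity; this specific functional form is a modelling choice (the
measured trend constrains only its direction). Desensitization is a single
multiplicative step: five opening time constants after light onset (when the
rise is >99% complete) the target steps down by the steady/peak ratio $R$.
There is no second kinetic state and no light–dark adaptation history.
Closing after light-off is a single exponential with $\tau_\mathrm{off}$.

**Membrane voltage.** A two-conductance membrane,
$$C_m \frac{dV}{dt} = -g_\mathrm{leak}(V - E_K) - g_\mathrm{max}\,a\,(V - E_\mathrm{ops}),$$
with a potassium-dominated leak so the resting potential is $E_K = -70$ mV.
The compartment is non-spiking: no voltage-gated sodium or calcium
conductances are modelled, which matches voltage-clamped or
inward-rectifier-polarized cells and is an explicit simplification for
neurons.

**Proton flux and pH.** The proton component of the photocurrent is a fixed
fraction $f_H$ of the instantaneous opsin current,
$I_H = f_H\,g_\mathrm{max}\,a\,(V - E_\mathrm{ops})$; only the inward part
acidifies. pH evolves as
$$\frac{d\,\mathrm{pH}}{dt} = \frac{\min(I_H, 0)}{F\,\mathcal{V}\,\beta} +
  k_\mathrm{rec}(\mathrm{pH}_\mathrm{rest} - \mathrm{pH}),$$
with $F$ the Faraday constant, $\mathcal{V}$ the compartment volume and
$\beta$ the buffering capacity. Because $I_H$ is a membrane flux, the
acidification rate at fixed current density scales exactly with the
surface-to-volume ratio (3/r for spheres, 2/r for cylinders): a 1-µm
dendrite acidifies 6.67× faster than a 10-µm soma, which the test suite
asserts to integrator precision. $f_H$ is a lumped phenomenological
parameter, not a GHK permeability — the package quantifies acidification,
not absolute proton selectivity. Proton extrusion (exchanger activity) is
first-order relaxation to resting pH; the experimental observation this
encodes is slow, partial recovery, with no commitment to a mechanism.

**Sensor.** The pH indicator follows a Hill (base-10, i.e.
Henderson–Hasselbalch) curve
$F = F_\mathrm{max}/(1 + 10^{\,n(pK_a - \mathrm{pH})})$, brighter at higher
pH, with $pK_a = 7.5$ and $n = 1$ by default. Blue stimulation light
photoactivates this class of red-shifted sensor independently of pH; the
model adds an artifact term linear in cumulative blue dose. Whether the real
artifact saturates is unknown; linear accumulation is assumed and isolated
in a single rate parameter.

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| soma radius | 10 | µm | typical cultured-neuron soma |
| dendrite radius | 1 | µm | thin process; surface/volume = 2 µm⁻¹ |
| $C_m$ | 20 | pF | small cell |
| $g_\mathrm{leak}$ | 3 | nS | resting input resistance ~330 MΩ |
| $E_K$ | −70 | mV | potassium-dominated rest |
| $\beta$ | 20 | mmol L⁻¹ pH⁻¹ | typical cytosolic buffering; no measured value exists for these cells, so an order-of-magnitude standard is used and exposed in config |
| $k_\mathrm{rec}$ | 0.003 | s⁻¹ | recovery half-time ≈ 230 s, well beyond a 150-s observation window |
| $g_\mathrm{max}$ (reference opsin) | 20 | nS | ~1300 pA steady photocurrent at −65 mV driving force |
| $f_H$ | 0.5 / 0 | — | proton-permeable reference vs engineered low-proton variants |
| sensor artifact rate | 0.0044 | ΔF/F per J cm⁻² | calibrated so an opsin-negative control accumulates +0.11 ΔF/F over the standard 150-s protocol at 500 mW cm⁻² — a deliberate anchoring of the artifact scale, not a prediction |

With these defaults the standard interleaved protocol (0.5 s stimulation /
1 s imaging for 150 s, then 150 s recovery) acidifies the default soma by
≈0.46 pH units at 150 s, inside the experimentally observed range; the
defaults were fixed once against that envelope and are not per-experiment
dials.

## The monolayer model

Confluent cells coupled by gap junctions are modelled as lumped nodes on a
square lattice (pitch 20 µm, 4-neighbor ohmic coupling, no-flux
boundaries). This reproduces continuum electrotonic behavior whenever the
length constant $\lambda = \mathrm{pitch}\sqrt{g_\mathrm{gap}/g_\mathrm{leak}}$
is much larger than the pitch. $\lambda \approx 300$ µm is a literature
value for such monolayers, and no measurement in this workflow pins down
$g_\mathrm{gap}$ and $g_\mathrm{leak}$ separately; the pair (450 nS, 2 nS)
was chosen to reproduce that $\lambda$ and is a documented implementation
choice.

Voltage equilibrates in milliseconds while acidification accumulates over
seconds, so `simulate_monolayer()` exploits timescale separation: the
voltage field is relaxed to steady state with the explicit `step_field()`
update (stability bound $2C_m/(g_\mathrm{leak} + g_\mathrm{max} + 8g_\mathrm{gap})$,
the 8 coming from the extreme eigenvalue of the 2D 5-point Laplacian), then
pH is integrated on the frozen field — exactly, per cell, when gap-junction
proton exchange is off. Proton diffusion through gap junctions is orders of
magnitude slower than voltage spread, so its rate constant defaults to 0,
with a config knob for sensitivity analysis.

Striped illumination (95-µm stripes and gaps, quantized to cell centres)
separates two hypotheses: if protons enter through the opsin, acidification
follows the illumination pattern sharply even though depolarization is
nearly uniform (off-stripe cells reach >97% of the on-stripe depolarization
at these parameters); if protons entered through a voltage-gated conductance
present in every cell, acidification would follow the smooth voltage
profile. The latter is implemented as an explicit, clearly-labelled
counterfactual mode (`proton_mode = "voltage_gated"`, sigmoidal activation
at −50 mV, 5-mV slope) used only to demonstrate the discriminating power of
the striped design — simulated contrast ratios are >100 for the opsin path
versus ≈0.95 for the counterfactual.

## The analysis pipeline

The pipeline mirrors how interleaved stimulation/imaging recordings are
analysed:

1. **Epoch collapsing** — camera frames during stimulation are discarded;
   frames within each imaging epoch are averaged and timestamped at the
   epoch midpoint. The recovery phase keeps the active phase's cadence
   (dark epochs replacing stimulation), so collapsed traces have uniform
   1.5-s resolution under the standard protocol.
2. **Baseline masking** — ΔF/F is computed only over signal-bearing pixels.
   The default threshold is the median of nonzero pixels of the baseline
   frame (the comparison is `>=`, so a uniform frame keeps every pixel);
   absolute and Otsu rules are available.
3. **ΔF/F extraction** — per-epoch ROI means against the first collapsed
   frame.
4. **Photoartifact subtraction** — the epoch-wise mean ΔF/F of
   opsin-negative control ROIs is subtracted from expressing ROIs. The
   operation is linear, so correcting then averaging equals averaging then
   correcting. Subtraction happens in ΔF/F space, before pH conversion;
   the original order of operations is not documented anywhere, and this
   choice keeps the correction independent of the calibration.
5. **Calibration** — a monotone piecewise-linear (pH, ΔF/F) map anchored at
   pH 7.3 where ΔF/F = 0. Non-monotone or duplicate knots are rejected.
   ΔF/F values beyond the knot range are clamped to the end knots and
   flagged per sample rather than extrapolated, because linear extrapolation
   of a saturating sensor is unbounded and misleading. Initial pH is assumed
   7.3 for every cell (overridable per ROI); analyses concern relative
   changes, so modest deviations shift curves without changing comparisons.
6. **Kinetics** — the acidification half-time is the first time the signal
   reaches half its maximum decrease within the stimulation window, linearly
   interpolated between the bracketing epochs (the interpolation rule is a
   documented choice; epoch resolution alone would quantize half-times to
   1.5 s). Recovery is fit with a single exponential
   $y_\infty + (y_0 - y_\infty)e^{-(t-t_0)/\tau}$; half-recovery is
   $\tau\ln 2$.
7. **Statistics** — two-sided Wilcoxon tests (rank-sum unpaired, signed-rank
   paired), exact for small tie-free samples (unpaired ≤10 per group,
   paired ≤15) and normal approximation with tie/continuity correction
   otherwise. Sidedness is not documented in the workflows this mirrors;
   two-sided is the conservative default. The exact path is validated in the
   tests against full enumeration of rank assignments.

### A sharp edge: calibration interpolation error

With the default sensor ($pK_a$ 7.5, Hill 1) and calibration knots at
{6.4, 6.7, 7.0, 7.3}, the worst-case round-trip error of piecewise-linear
inversion is 0.0205 pH, attained near pH 6.55 where the base-10 titration
curve is most curved between knots. This is a property of the knot spacing,
not of the implementation — the package reproduces the closed-form value to
three digits, and halving the knot spacing reduces the error to ~0.005 pH.
Calibrations aiming for accuracy better than 0.02 pH need knots finer than
0.3 pH units.

## Photocurrent characterization

Voltage-clamp recordings are smoothed with a centered moving average
(default width 5 samples; widths are odd and edges shrink symmetrically).
From a saturating step: the peak current, the steady-state current (mean of
the last 20% of the light window — the averaging window is a documented
choice), and their ratio. The package computes and labels the
steady-state/peak ratio (1.00 = sag-free); published tables sometimes head
this column "peak/steady-state" while listing values ≤1, and the explicit
labelling avoids that ambiguity. Gating time constants come from
single-exponential least-squares fits (Levenberg–Marquardt via `minpack.lm`,
log-linear initialization, and a perturbed restart that guards against the
rank-deficient Jacobian an exact-fit start produces on noiseless data). A
fit is flagged as misspecified when its residual RMSE exceeds five times a
robust noise estimate from raw first differences — a relative-RMSE threshold
cannot work here, because a free-offset single exponential fits bi-exponential
decays to ~3% while honest noise at SNR 10 contributes 10%.

Light sensitivity is fit with the saturation law
$I_{ss}(P) = I_\mathrm{max} P/(P + \mathrm{EPD50})$ with optional seeded
bootstrap confidence intervals. Reversal potentials are linearly
interpolated between the bracketing holding voltages; with no sign change
extrapolation is refused, and with multiple crossings the one nearest 0 mV
is returned, flagged. Action spectra normalize to the 488-nm current with a
0.3% detection floor (values below it are censored, reported as "< floor").
Ion-substitution selectivity uses the ideal Nernst shift
$\Delta V_r = (RT/zF)\ln(c_\mathrm{after}/c_\mathrm{before})$; the
selectivity index is the measured/ideal ratio, and absolute GHK permeability
ratios are deliberately not computed.

## What the synthetic generator does and does not emulate

The generator produces interleaved-protocol image stacks with circular ROIs,
Poisson-free Gaussian pixel noise, a near-zero background, the blue-light
photoartifact in opsin-negative cells, and ground-truth masks and traces —
everything needed to test the pipeline's arithmetic end to end. It does not
emulate motion, photobleaching beyond the artifact term, spiking, cell-shape
irregularity, focus drift, intracellular pH gradients (compartments are well
mixed; no diffusion PDE), calcium dynamics, or multi-state photocycles.
Passing tests therefore validate the analysis chain and the model's internal
consistency, not the biological completeness of the model: real recordings
bring nuisance structure the generator deliberately omits.

## Numerical choices and problem sizes

Integration is fixed-step explicit Euler with validated stability bounds
(voltage: $dt \le 2C_m/g_\mathrm{tot}$; violations raise errors naming the
bound). The default compartment step is a quarter of the bound, capped at
0.5 ms; the gate uses exact exponential relaxation per step. Determinism is
part of the contract: a seed fixes every random draw, and identical seeds
give bitwise-identical traces.

The test suite runs compartment simulations of 15–300 s, monolayers up to
100×100 cells, populations of 25 cells per group, and 50-replicate fitting
studies; these sizes were chosen so the full suite completes in well under a
minute of compute while keeping every statistical check adequately powered
(e.g. the 25-vs-25 population comparison has rank-sum p ≈ 1e-10 at the
simulated effect size).

## Known limitations

* $f_H$ is constant: proton flux tracks total current with no
  voltage-dependent selectivity and no GHK rectification.
* The compartment never spikes; neuronal acidification under spiking
  stimulation is outside the model.
* Desensitization is a single step; opsins with pronounced bi-exponential
  sag or light-dark adaptation need a richer photocycle.
* The monolayer assumes homogeneous coupling and expression; heterogeneous
  gap-junction maps are not modelled.
* The sensor's artifact accumulates linearly without saturation; long or
  intense protocols may overstate it.
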