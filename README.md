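# photoacid

Simulation and analysis of optogenetically induced intracellular
acidification.

Channelrhodopsins — the light-gated cation channels used throughout
optogenetics — conduct protons as well as Na⁺ and K⁺. A polarized cell has a
large inward proton-motive force, so opening a proton-permeable channel
acidifies the cytosol; repeated stimulation can shift intracellular pH by
half a unit or more, a threefold rise in free protons. `photoacid` is for
experimenters and tool builders who quantify this effect from fluorescence
pH imaging, and for anyone validating such a pipeline against synthetic data
with known ground truth.

## What the package computes

The core forward model couples, in a single well-mixed compartment:

* an opsin gate with first-order kinetics, activation
  `a∞ = s(λ)·P/(P + EPD50)`, intensity-dependent opening
  `τ_on(P) = τ_on,sat·(1 + EPD50/P)`, single-step desensitization and
  exponential closing;
* a two-conductance membrane, `C_m dV/dt = −g_leak(V − E_K) − g_max·a·(V − E_ops)`;
* proton flux and buffering,
  `d(pH)/dt = min(I_H, 0)/(F·V·β) + k_rec·(pH_rest − pH)` with
  `I_H = f_H·g_max·a·(V − E_ops)`, so acidification scales with the
  compartment's surface-to-volume ratio;
* a pH sensor with a base-10 Hill response (pKa 7.5), a blue-light
  photoartifact linear in cumulative dose, and Gaussian noise.

Around it:

* `simulate_cell()`, `render_movie()` — synthetic traces and image stacks
  with ground truth;
* `simulate_monolayer()`, `stripe_pattern()`, `acidification_contrast()` — a
  gap-junction-coupled 2D monolayer (electrotonic length constant ≈ 300 µm)
  under striped illumination, including the voltage-gated-proton
  counterfactual the striped design is built to reject;
* `collapse_epochs()`, `f0_mask()`, `extract_trace()`,
  `subtract_artifact()`, `build_calibration()`, `dff_to_ph()`,
  `half_time_acid()`, `fit_recovery()`, `compare_groups()`,
  `analyze_stack()` — the image-to-kinetics analysis chain;
* `simulate_photocurrent()`, `peak_steady()`, `fit_tau()`, `fit_epd50()`,
  `reversal_potential()`, `nernst_shift()`, `action_spectrum()`,
  `crosstalk()`, `characterize_opsin()` — voltage-clamp photocurrent
  characterization.

See `vignette("photoacid-methods")` (source under `vignettes/`) for the
models, defaults and numerical choices.

## Worked example

Simulate the standard interleaved protocol (0.5-s blue stimulation / 1-s
imaging for 150 s, then 150 s recovery) for a proton-permeable opsin in a
10-µm soma, and summarize the kinetics:

```r
library(photoacid)
tr <- simulate_cell(protocol = build_protocol(0.5, 1, 150, 150))
print(tr)
#> Simulated compartment trace: 690001 samples over 300 s (dt = 0.0004347826 s)
#>   pH 7.300 -> min 6.842 (final 7.009); V rest -70.0 mV, min -70.0 mV

kin <- roi_kinetics(data.frame(t = tr$t, pH = tr$pH), c(0, 150), c(150.5, 300))
#> pH_min 6.842  t_half_acid 66.2 s  tau_rec 333 s  t_half_rec 231 s
proton_fold_change(7.3, kin$pH_min)
#> 2.87
```

The cell acidifies by ~0.46 pH units over 150 s of interleaved stimulation
(about a threefold rise in free protons), then recovers only partially —
the extrusion time constant (333 s) is much longer than the observation
window, so 150 s of recovery returns the cell to pH 7.01, not 7.3.

Characterize a fast low-proton-permeability opsin from synthetic
voltage-clamp recordings:

```r
characterize_opsin(opsin_preset("pscatch2"))
#> Opsin gating characterization
#>   Reversal potential:     12.3 mV
#>   tau_on (saturating):   4.243 ms
#>   tau_on (at EPD50):     8.401 ms
#>   tau_off:                17.6 ms
#>   EPD50:                 115.7 mW cm^-2
#>   Steady-state current:  -824.6 pA
#>   steady/peak ratio:     0.9263
```

Every fitted number is within a few percent of the generating parameters —
the characterization chain is validated by this self-consistency.

Compare two small groups of final-pH values (proton-permeable vs not):

```r
compare_groups(c(6.7, 6.9, 6.8, 7.0, 6.6), c(7.28, 7.31, 7.30, 7.29, 7.32))
#> Wilcoxon rank-sum test: W = 0, p = 0.00794 (exact), n = 5 vs 5
```

A command-line entry point wrapping these functions is installed at
`inst/cli/photoacid.R` with subcommands `simulate-cell`,
`simulate-monolayer`, `analyze`, `ephys-fit`, `fixtures` and `report`.

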