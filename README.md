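# kcnqres

Conductance-based modelling and analysis of KCNQ (Kv7) channel gating and
membrane resonance.

## The scientific problem

Neurons and heterologous cells expressing slow voltage-gated K⁺ channels can
act as band-pass filters: injected oscillatory current produces the largest
voltage response at a preferred *resonant frequency*. In circuit terms the
membrane behaves like a parallel RLC circuit, with slow channel gating playing
the role of a *phenomenological inductor*. M-type KCNQ (Kv7) channels produce
such resonance-like responses, but — unlike ERG-family (Kcnh) channels — they
lack rapid inactivation, and with it two signatures of true inductor-like
behaviour: the *opposing conductance change* at voltage-step transitions and
cell-autonomous membrane-potential oscillation.

`kcnqres` is for computational neurophysiologists who want to simulate and
analyse these phenomena without a full NEURON installation. It provides:

- **Channel models.** Hodgkin–Huxley-style KCNQ kinetics,
  `g = gmax · m⁴` with

  ```
  m∞(V)  = 1 / (1 + exp[(θ_m − V)/k_m])
  τ_m(V) = τ_m0 + (τ_m1 − τ_m0) / (exp[(φ_m − V)/σ_m0] + exp[(φ_m − V)/σ_m1])
  dm/dt  = (m∞(V) − m) / τ_m(V)
  ```

  and a rapid-inactivation variant `g = gmax · m⁴ · h`, where `h` follows the
  same kinetic form with a floor `h_min` (`h∞ = h_min + (1 − h_min)/(1 +
  exp[(θ_h − V)/k_h])`, `k_h < 0`).
- **A single-compartment cell** (40 × 40 µm cylinder, `g_pas` = 1.4 × 10⁻⁵
  S/cm², `cm` = 5 µF/cm², E_K = −97.5 mV → input resistance 947 MΩ).
- **Protocols and simulators**: voltage-step families, sinusoidal clamp, and
  ZAP chirp currents (50 pA, 0–40 Hz over 40 s), integrated with exact
  exponential gate relaxation plus backward-Euler voltage updates (Rcpp).
- **Analyses**: impedance profiles `Z(f) = FFT(V)/FFT(I)` with
  forward/reverse-chirp averaging, resonant frequency (argmax of |Z| above
  0.5 Hz) and resonant strength (peak/|Z(0.5 Hz)|), opposing-conductance step
  metrics, Welch-PSD oscillation detection, Boltzmann G–V and
  single-exponential kinetic fits, and blocker-subtraction difference
  currents.
- **A reference RLC circuit with a leaky inductor** (R = 100 MΩ, C = 200 pF,
  L = 10 MH, R_L = 30 MΩ, Re = 5 MΩ), analytic and simulated, as the
  ideal-inductor oracle.
- **A synthetic recording generator** (channel current + leak + Gaussian
  noise, paired control/blocker sweeps, parameter-level mutants) so every
  analysis stage is testable without experimental data.

The packaged channel kinetics are a documented synthetic reconstruction (see
`inst/extdata/kcnq_params_synthetic.yaml` and the methods vignette).

## Worked example

```r
library(kcnqres)

cell <- cell_model(channels = list(kcnq_model()))
cell
#> <cell_model> 40 x 40 um cylinder (+caps), g_pas 1.4e-05 S/cm^2, cm 5 uF/cm^2
#>   e_pas -60 mV, E_K -97.5 mV, R_in 947 MOhm, C 377 pF, 1 channel(s)

# ZAP impedance profile at a depolarized holding potential
zap <- zap_impedance(cell, holding_mV = -40)
zap$metrics
#> <resonance_metrics> f_res = 12.3 Hz, strength = 2.892 (|Z| 10.7 -> 30.9 MOhm)
```

The KCNQ cell resonates: the impedance peaks at an interior frequency
(12.3 Hz) and the peak is 2.9× the impedance at 0.5 Hz. A passive cell run
through the same pipeline gives `f_res = 0.5 Hz, strength = 1.000` — the
non-resonant control.

The rapid-inactivation variant adds the inductor-like signatures:

```r
cell_i <- cell_model(channels = list(kcnq_inactivation_model()))

# opposing conductance transients at a +10 mV step from -30 mV
cmd <- build_voltage_steps(-30, -20, pre_ms = 2000, step_ms = 2000,
                           post_ms = 500, dt = 0.02)[[1]]
sim <- run_voltage_clamp(cell_i, cmd)
step_metrics(sim$conductance, dt = 0.02, onset_ms = 2000, offset_ms = 4000)
#> onset transient: -0.192, offset transient: +0.281 (relative)

# sustained membrane-potential oscillation at a depolarized plateau
osc <- oscillation_response(cell_i, target_mV = -25)
psd <- power_spectrum(osc$V)
psd
#> <psd_result> peak 135 mV^2/Hz at 4.40 Hz (in-band median 3.77e-05)
detect_oscillation(psd)
#> [1] TRUE
```

The conductance transiently *drops* 19% at the depolarizing onset and
*overshoots* 28% at the offset (the opposing change), and the same cell
oscillates at ~4.4 Hz after a depolarizing current step — the plain KCNQ cell
does neither.

Ready-made scenario configurations (ZAP, voltage steps, oscillation, RLC,
synthetic pairs) live in `inst/extdata/scenarios/` and run via
`run_scenario()`.

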