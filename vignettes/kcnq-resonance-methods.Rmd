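---
title: "Methods: KCNQ gating, membrane resonance and oscillation in kcnqres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KCNQ gating, membrane resonance and oscillation in kcnqres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, its numerical
choices, and the design decisions taken where the design was genuinely open.

## The membrane model

The cell is a single isopotential compartment:

$$C_m \frac{dV}{dt} = -g_{pas}(V - e_{pas}) - \sum_i g_i(V, t)\,(V - E_K) + I_{inj}$$

with a cylindrical geometry (default 40 µm diameter × 40 µm length),
specific leak conductance $g_{pas}$ (1.4 × 10⁻⁵ S/cm²), specific capacitance
$c_m$ (5 µF/cm²), resting potential $e_{pas}$ (−60 mV) and K⁺ reversal
$E_K$ (−97.5 mV in simulations). Cytoplasmic resistivity `Ra` is stored so NEURON-style
model definitions round-trip, but plays no role in one compartment.

**Area convention.** The default surface area *includes both end caps*
($1.5\pi d^2$ for the default geometry). This is the only convention under
which the default leak density and geometry reproduce the canonical 947 MΩ
input resistance of the HEK-like cell (a cap-less cylinder gives ≈1421 MΩ);
a flag provides the lateral-only (NEURON-style) area. With caps the total
capacitance is 377 pF and the passive time constant $c_m/g_{pas}$ ≈ 357 ms,
placing the passive cut-off near 0.45 Hz — which is why the passive cell's
impedance declines monotonically over the whole 0.5–40 Hz analysis band.

**Two reversal conventions.** Simulation-side analyses use $E_K = −97.5$ mV;
experimental-style conductance calculations use the Nernst value −98 mV
implied by the whole-cell solutions (2.5 mM external K⁺, 115 mM
K-methanesulfonate + 5 mM KCl = 120 mM internal) at 22 °C room temperature.
Both are explicit defaults rather than one global constant. The temperature
for the −98 mV figure is a reconstruction: recordings at "room temperature"
are taken as 22 °C, which reproduces −98 mV to the nearest millivolt.

## Channel gating

Both channel models use Boltzmann steady states and double-sigmoid
voltage-dependent time constants:

$$x_\infty(V) = x_{min} + \frac{1 - x_{min}}{1 + e^{(\theta - V)/k}},\qquad
\tau_x(V) = \tau_0 + \frac{\tau_1 - \tau_0}
{e^{(\phi - V)/\sigma_0} + e^{(\phi - V)/\sigma_1}}$$

The plain KCNQ model is $g = g_{max} m^4$ ($x_{min}=0$, $k>0$); the
rapid-inactivation variant multiplies by a single inactivation gate,
$g = g_{max} m^4 h$, with $k_h < 0$ and a non-zero floor $h_{min}$ so the
channel never inactivates completely. Gate exponents (4 and 1) follow the standard
product forms for these channels and are overridable in the parameter file.

### Provenance of the default parameters — a synthetic reconstruction

The packaged parameter file is named `kcnq_params_synthetic.yaml`
deliberately. The activation gate follows the published lineage of
globus-pallidus KCNQ kinetics (midpoint −61 mV, slope 19.5 mV, τ between
6.7 and 100 ms, fourth-power gate); note that with $m^4$ this places the
*conductance* midpoint near −29 mV, consistent with whole-cell G–V fits for
KCNQ2/3. The rapid-inactivation gate could not be sourced numerically, so it
was constructed once, before the test suite was frozen, to express the
qualitative behaviours the inactivating model must show:

- rapid inactivation and recovery (τ_h 1.5–8 ms, an order of magnitude
  faster than τ_m over the operating range);
- a depolarized midpoint (θ_h = −25 mV, k_h = −6 mV) so the negative-slope
  region of the steady-state I–V curve covers plateaus of roughly −30 to
  −15 mV but leaves −40 mV stable — the cell must still yield a clean chirp
  response at −40 mV;
- a shallow floor (h_min = 0.38). The floor height controls the conductance
  on the depolarized branch of the fast subsystem: a deep floor lets a
  depolarizing current step escape to a stable far-depolarized fixed point
  instead of oscillating, while a shallow floor keeps the limit cycle
  bounded at tens of millivolts. The value was chosen from a linearized
  stability analysis of the (V, h) fast subsystem with m slow, then verified
  by simulation.

With this set the inactivating cell sustains a limit-cycle oscillation for
current steps sized for −30 to −15 mV plateaus and is quiescent at −40 mV;
the plain KCNQ cell never oscillates. One known infidelity: at a +10 mV step
from −30 mV the inactivating model's current *overshoots* below the pre-step
baseline before the slow rise, rather than rising cleanly from baseline. The
overshoot is a direct consequence of Δh∞ slightly exceeding Δm⁴∞ across that
step for this parameter set; the qualitative contrast (the step current is
cancelled within ~10 ms in the inactivating model and sustained in the plain
model) is unaffected, and the tests assert that contrast rather than a
specific overshoot shape.

## Numerical integration

Gates are advanced by the *exact* exponential relaxation
$x \leftarrow x_\infty + (x - x_\infty) e^{-\Delta t/\tau}$, which solves the
gate ODE exactly for piecewise-constant voltage and keeps every gate inside
$[x_{min}, 1]$ unconditionally. The membrane voltage uses backward Euler
with the freshly updated conductances (operator splitting per step). The
scheme is first-order, unconditionally stable, and standard for this model
class; `dt` defaults to 0.01 ms in voltage clamp and 0.025 ms in current
clamp, both configurable. The test suite verifies that halving `dt` changes
simulated traces by less than 0.5% of their range on the shipped step and
chirp scenarios; for the *oscillating* scenario a sample-wise bound is not
meaningful (phase drifts with `dt` on a limit cycle), so convergence there
is asserted on the reported metrics instead.

Voltage clamp is ideal: the command is imposed exactly, series resistance
and capacitance compensation are not modelled, and the reported current is
the ionic channel current only.

## ZAP impedance analysis

The chirp is $I(t) = \pm A \sin\!\big(2\pi(f_0 t + (f_1 - f_0)t^2/2T)\big)$
(default 50 pA, 0→40 Hz, 40 s), starting as a sine so the stimulus begins at
baseline rather than with a step; the sine-versus-cosine phase is a package
convention. Every protocol prepends a 2 s settling epoch at the
holding bias so gates equilibrate before the analysed window.

Impedance is $Z(f) = \mathrm{FFT}(V)/\mathrm{FFT}(I)$ per FFT bin, magnitude
$\sqrt{Z_{Re}^2 + Z_{Im}^2}$, with three numerical safeguards:

- **Decay tail.** The analysis window is the chirp plus a 2 s zero-stimulus
  tail. Truncating the response at the chirp's end biases the spectral ratio
  broadly (≈0.8% for the passive cell, dt-independent); letting the
  transient decay inside the window removes it (residual < 0.01%).
- **Stimulus-power floor.** Bins where $|\mathrm{FFT}(I)|$ is below 1% of
  its band maximum are masked, not divided.
- **Nearest-bin convention.** $|Z(0.5\,\mathrm{Hz})|$ is the bin nearest
  0.5 Hz with no interpolation; with 40 s + 2 s windows the bin spacing is
  1/42 Hz and 0.5 Hz is an exact bin.

The forward and phase-reversed chirps are averaged as the pointwise mean of
the two *magnitude* spectra — with complex averaging
available behind a flag. No spectral
smoothing is applied by default. Resonant frequency is the argmax of $|Z|$
over [0.5, 40] Hz; resonant strength is that maximum divided by
$|Z(0.5\,\mathrm{Hz})|$, so a monotonically decreasing profile scores
(0.5 Hz, 1.0) by construction.

`conductance_vs_frequency` reports the per-cycle mean channel conductance
(cycle boundaries from the chirp's analytic phase) normalized to the
pre-stimulus baseline; for a passive-only run the total membrane conductance
is used so the curve is identically 1. At the standard 50 pA amplitude the
voltage excursions are only 1–3 mV, so cycle-mean modulation is a
second-order effect: the plain KCNQ decline with frequency resolves, but the
inactivating model's band-limited elevation near resonance is below
resolution with the reconstructed parameters and is not asserted by tests.

## Step, sinusoid and fitting analyses

**Opposing transients.** `step_metrics` takes steady levels as the mean over
the last 20% of each epoch and searches a 50 ms window after each transition
(both windows are operationalizations and are configurable). The reported transient is the signed extremum in the
*opposing* direction — minimum at a depolarizing onset, maximum at offset —
so a channel that merely activates slowly scores ≈0 rather than registering
its own rise as a transient. Decrease at a depolarizing onset is negative.

**Sinusoid metrics.** Amplitude is half the bottom-to-top excursion over the
steady cycles (first cycle discarded); outward/inward amplitudes are
measured from the pre-stimulus holding mean, the package's baseline
convention.

**Fits.** Both fitters use Levenberg–Marquardt (minpack.lm).
`fit_exponential` initializes the offset from the tail mean and τ from a
log-linear regression over the early, signal-dominated part of the decay
(samples above 20% of the peak deviation), clamped to [dt, segment length]
so the initial Jacobian cannot become collinear in the flat-τ limit; bounds
keep τ in (0, 10 × segment length]. The 10–90% rise time of a fitted
exponential is τ·ln 9. `fit_boltzmann` fits $G/G_{max} = 1/(1 +
e^{(V_{half} - V)/k})$, optionally with $G_{max}$ fixed at 1; fits on data
that do not span the transition (or that hit the iteration limit) are
flagged `low_confidence` rather than rejected. Seeded recovery suites in the
tests: τ within 5% in ≥95% of 200 runs at 5% noise; $V_{half}$ within ±2 mV
in ≥90% of 200 runs at 5% multiplicative noise on 9 levels.

**Driving-force guard.** Conductance-from-current masks samples within 1 mV
of $E_K$ instead of dividing.

## Oscillation detection

The PSD estimator is Welch averaging — segments of a quarter of the trace,
50% overlap, Hann taper, linear detrend first; a plain periodogram is
available by setting one segment. Detection
requires (i) the in-band (0.5–40 Hz) peak to be ≥20× the in-band median PSD,
(ii) the same prominence at a nearby frequency in *both* halves of the
trace, and (iii) the second half to retain ≥25% of the first half's peak
power. The third condition exists because deterministic simulations have no
noise floor: a decaying subthreshold ring can dominate its own median by
orders of magnitude while vanishing in absolute terms, and the
decay-between-halves test is what separates a damped resonance from a
sustained limit cycle. Detection is invariant to DC offsets by construction
(detrending), and a numerically flat trace short-circuits to `FALSE`.
Analysis windows are ≥10 s with the first 2 s after the step discarded.

## The RLC reference circuit

The analytic form is $Z(f) = R_e + \big[R \,\|\, (R_L + j\omega L) \,\|\,
1/(j\omega C)\big]$ with defaults R = 100 MΩ, C = 200 pF, L = 10 MH,
R_L = 30 MΩ, Re = 5 MΩ. Units are MΩ/pF/MH/nA/mV so the inductor time
constant $L/R_L$ lands at 333 ms naturally. Two clamp variants are
provided, since either clamp point is defensible for a recording-electrode
circuit: an ideal node clamp (which yields the closed-form
$\Delta I_L(t) = (ΔV/R_L)(1 - e^{-tR_L/L})$ and is the analytic oracle) and
a clamp through Re as the circuit is drawn. The two-state simulation uses
backward Euler; the capacitor current is reported from the same backward
difference the implicit step solves, so Kirchhoff's current law holds to
machine precision at every sample rather than to finite-difference accuracy.

## The synthetic recording generator

`make_paired_recordings` emulates a paired control/blocker experiment:
channel current + linear leak + i.i.d. Gaussian noise, with the blocker
sweep scaling the channel current by $1 - \text{block fraction}$ and drawing
independent noise. It is a pure function of (spec, seed) and restores the
caller's RNG state. What it deliberately does *not* emulate: series/access
resistance artifacts, capacitance transients, electrode drift,
activity-dependent block kinetics (the blocker is a static conductance
scale), or realistic noise spectra (recording noise is not white). Passing
tests on these fixtures therefore demonstrates estimator correctness under
the stated statistical model, not robustness to real recording artifacts.
Mutants are emulated at parameter level only (midpoint shift, τ scaling);
`make_ica_variant` removes the inactivation gate outright, emulating
pharmacological suppression of rapid inactivation.

## Scenario orchestration

`run_scenario` executes simulate-then-analyse from a single YAML config
(unknown keys rejected), writing trace CSVs, a metrics JSON and a run log
carrying the package version, seed and full config, so reruns are
reproducible byte-for-byte. The CSV trace dialect is
`time_ms,<quantity>_<unit>` with a uniform time base enforced on read. This
package is a library, not a shell tool: the exported functions, the shipped
scenario configs and `scripts/acceptance.R` are its entry points.

## Problem sizes

The test suite and acceptance script run full-length protocols where the
analysis depends on them (40 s chirps + 2 s settle + 2 s tail at
dt = 0.025 ms; 12 s oscillation steps) and shortened epochs elsewhere
(0.5–2 s steps, 5 s chirps for convergence checks, 200-seed Monte-Carlo
suites for the fitters). The full suite completes in about half a minute on
one CPU.

## Known limitations

- The h-gate parameter set is a reconstruction; quantitative figures that
  depend on it (oscillation frequency and amplitude, resonant frequencies of
  the channel-bearing cells) characterize *this* parameter set, not the
  source model, and experimental means from real cells are emulation
  targets, not reproduction targets.
- Single compartment only; no Markov gating, temperature (Q10) scaling, or
  PIP₂/phosphorylation modulation.
- Phase-based resonance measures (phase-lead crossing frequency) are not
  computed.
- The impedance pipeline assumes the response window captures an
  approximately linear, settled system; strongly oscillating cells violate
  this and are excluded from resonance analysis, matching experimental
  practice.
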