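---
title: "Optogenetic current clamp: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optogenetic current clamp: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(optoclamp)
```

`optoclamp` simulates and analyses optogenetic current-clamp measurements
of cardiac excitability. This vignette documents the science in the
package: the two coupled models, the measurement protocols and their
tunable parameters, the synthetic-data generators, the numerical choices,
and the known limitations. It states no empirical numbers beyond those
the package's tests and acceptance script themselves compute.

## The ChR2 photocurrent model

Channelrhodopsin-2 (H134R) is modeled as a four-state photocycle: two
open states `o1`, `o2` (the second with relative conductance
`gamma = 0.1`) and two closed states `c1`, `c2`. Light drives
`c1 -> o1` and `c2 -> o2` at rates proportional to the absorbed-photon
rate `k_flux * E * p`, where `E` is irradiance (uW/mm^2 at 465 nm) and
`p` is a fast activation variable (time constant 1.3 ms) that switches on
with light. The inter-open transitions `o1 <-> o2` increase
logarithmically with photon flux; `o1` closes with a voltage-dependent
rate (faster at depolarized potentials), `o2` closes to `c2`, and `c2`
returns to `c1` with a slow, voltage-dependent recovery rate (seconds at
diastolic potentials) — this slow pool is what produces peak-current
desensitization under repeated stimulation. The open-channel current
follows an empirical rectification `I = g * (r0 - r1 e^{-V/rk}) *
(o1 + gamma o2)`, inward (negative) below the ~+13.6 mV reversal.

Two light-dependence constants (the flux normalization of the activation
switch and of the inter-open rates) are exposed in `chr2_params()` with
defaults chosen so the model activates across the experimentally used
irradiance range (~10 to ~800 uW/mm^2). Their absolute scale is not
critical because the conductance scale `g_chr2` is always recalibrated:
`calibrate_chr2()` pins the model to a measured patch-clamp constraint —
a 20-ms, 13.6-uW/mm^2 pulse at a holding potential of −75.4 mV must
produce a peak current density of −0.45 pA/pF. The photocurrent is
strictly linear in `g_chr2`, so one unit-conductance simulation plus an
exact rescaling suffices; the peak is the extremum of the current within
the pulse window. All calibrated and relative quantities downstream are
therefore insensitive to the absolute irradiance conversion.

## The cardiomyocyte model

Single-cell electrophysiology uses a murine ventricular myocyte model of
the Bondarenko type (apex parameter set): Markov chains for the fast Na+
channel, the L-type Ca2+ channel, the rapid delayed rectifier, a
four-state ryanodine-receptor model with subspace Ca2+ dynamics and
SR compartments, Hodgkin–Huxley gates for the transient outward and
ultrarapid K+ currents, and Na+/K+/Ca2+ concentration bookkeeping — about
40 state variables, implemented in C. The implementation was verified
against the published resting steady state: every Markov-chain occupancy
ratio, gate steady state and buffer equilibrium reproduces the published
initial conditions to five significant figures, and the quiescent model
drifts by less than 2e-4 mV over seconds.

The package adds the quantities this method manipulates:

* a cation background leak
  `I_leak = g_leak [(V - E_Na) - 0.5 (V - E_K)]` (K+ conductance one half
  of the Na+ conductance), used to depolarize the resting membrane
  potential the way constant ChR2 photocurrent does in the experiment;
* a parameterized inward rectifier
  `I_K1 = s_K1 * 0.2938 * K_o/(K_o + 210) * (V - E_K) / (1 + e^{ir (V - E_K)})`
  with tunable rectification exponent `ir` (source value 0.0896 mV^-1).
  The K+-binding term is evaluated with `K_o` in micromolar
  (5400/(5400+210)), the only reading that yields a functioning inward
  rectifier; the exported formula function `i_k1()` is unit-agnostic.
* multiplicative scale factors `s_K1, s_NaK, s_Nab, s_Na` and per-channel
  Hill block `1/(1 + (c/IC50)^h)` applied as a conductance scale. The
  bundled amiodarone/dronedarone/lidocaine tables are configuration data
  encoding the qualitative multichannel signatures (Na+ block with strong
  vs. weak inward-rectifier block vs. pure Na+ block); replace them via
  `drug_profile(channels = ...)` or a JSON config for quantitative work.

The ChR2 photocycle is integrated as part of the same state vector, its
current added to the membrane equation and its Na+ flux booked into the
intracellular Na+ balance.

### A metastable depolarized state

The model possesses a quasi-stable depolarized equilibrium near −33 mV,
sustained by a small persistent Na+ window current balanced against the
partially inactivated outward K+ currents. An action potential fired from
full rest into a strong sustained depolarizing drive (a long bright light
pulse, or a large background leak) can fail to repolarize and settle
there for seconds. This is a property of the ionic model itself, which is
why every protocol result is gated by an explicit stability rule
(`is_stable()`: the cell must return to the same diastolic potential
after each AP, with no spontaneous activity). Two protocol-design choices
keep the measurements inside the stable regime:

1. **Adaptive pacing intensity.** The S1 pacing pulse (10 ms) is set per
   condition to `pace_factor = 1.2` times that condition's own sustained
   capture threshold, found by an upward scan with short pulse trains.
   Within any paired family (with/without leak; the iterates of a
   root-finder) the intensity is resolved once from the leak-free
   reference and held fixed, so paired comparisons are paced identically.
2. **Two-phase conditioning.** The pacing rhythm is first established for
   three cycles without the background leak, then the leak is switched on
   for the `n_prepace = 10` conditioning cycles — mirroring the
   experimental sequence, in which depolarizing illumination is added
   during ongoing pacing. With this, leak depolarizations up to ~8 mV are
   stable; switching the leak on at rest destabilizes the first AP from
   about +3.5 mV.

## Measurement protocols

All protocols pace at a 275-ms cycle length and measure after 10
conditioning cycles; all options live in `protocol_options()`.

* **RMP** is the minimum membrane potential over one unpaced cycle length
  following the conditioning train. Measuring after the last stimulus
  keeps the statistic free of direct stimulus artifacts (the post-AP
  minimum during ongoing pacing shifts by ~0.1 mV per 10% change in
  pacing intensity; the post-train minimum by <0.01 mV).
* **R_m** delivers a 20-ms, 15-uW/mm^2 subthreshold pulse in deep
  diastole (onset 240 ms after the pacing pulse) and divides the maximal
  difference between the paired cycles (with/without the probe) by the
  peak probe photocurrent: `R_m = dE_max / I_ChR2`. The peak current is
  used rather than the current at the time of `dE_max` because the
  calibration constraint is itself a peak; percentage changes are always
  computed on the pA/pF scale, and megohm values use the 100-pF membrane
  capacitance convention. A probe that triggers an AP is rejected.
* **I_thr** is the lowest intensity at which 10 of 10 consecutive 10-ms
  pulses each trigger an AP (capture: V exceeds 0 mV within 50 ms of
  pulse onset), found by an upward geometric scan (failures are cheap —
  the train stops at the first missed capture) followed by bisection to
  1% relative tolerance inside the bracket [0.1, 800] uW/mm^2, the upper
  bound mirroring the maximum technically available intensity. The
  threshold is reported as the peak ChR2 current density of the last
  threshold pulse, which accounts for desensitization.
* **`calibrate_leak()`** root-finds `g_leak` for a requested RMP shift
  (tolerance 0.02 mV), treating loss of stability as overshoot;
  **`calibrate_ir()`** root-finds the rectification exponent so that a
  leak-induced depolarization raises R_m by a requested percentage,
  re-running the leak calibration at every iterate.
* **`sweep_modifier()`**, **`drug_response()`** and
  **`classify_intervention()`** map interventions onto the
  (dR_m, dI_thr) plane: quadrant I (both up), II (R_m up, I_thr down,
  the pro-arrhythmic direction), III (both down) and IV (R_m down,
  I_thr up, the anti-arrhythmic direction).

## Trace analysis

The experimental pipeline operates on 10-kHz membrane-potential
recordings with pulse annotations. Cycles are aligned on pacing-pulse
onsets and averaged pointwise; `delta_e()` takes the maximum of the
with-minus-without difference over the probe window plus 100 ms. Because
the maximum of a noisy trace is biased upward by the residual-noise
envelope, the difference is smoothed with a short (10 ms) moving average
first — well below the width of a passive response, and removable with
`smooth_ms = 0`.

AP phases: initiation is the time of maximal upstroke dV/dt; the
amplitude is peak minus the diastolic baseline (mean over 200–240 ms
after initiation); APD70/APD90 are the times to 70%/90% repolarization of
that amplitude (linear interpolation between samples); the plateau marker
is 0.5*APD70. Offset correction shifts a trace additively so its
diastolic mean equals the control RMP (−75.4 mV) plus any constant
light-induced depolarization. Recordings with AP amplitude below 70 mV or
electrode-resistance drift above 10 megohms are excluded; paired
comparisons require penetration depths within 80 um.

DAD detection smooths the pause segment with the 100-ms moving average,
then finds local maxima with a topographic-prominence criterion (three
times the post-filter residual noise, at least 50 ms apart); amplitudes
are peak minus flanking baseline. The event template used by the
generator (30-ms rise, 80-ms decay) is slower than the filter corner, so
amplitudes survive filtering attenuated by a known factor that the
generator records in its truth output.

## Space-constant estimation

The depolarization produced at the recording site by an illuminated
region `[far_edge, b]` is modeled as the convolution of the illumination
indicator with the electrotonic weight
`g(x, lambda) = (1/lambda)(2 - e^{-x/lambda}) e^{-|x|/lambda}`. The
convolution is evaluated in closed form (piecewise antiderivatives,
continuous across zero) and cross-checked against adaptive quadrature.
The printed weight is asymmetric and becomes negative for
`x < -lambda log 2`; an alternative with `|x|` in both exponentials is
available (`variant = "symmetric"`), every fit records which was used,
and the printed form is the default. Physically the illumination is a
bounded interval; the half-line mode (`far_edge = -Inf`) reproduces the
literal indicator and is well-defined at the recording site, though its
response decreases again once the near edge extends far past the
electrode — fits should keep edges within about one space constant of the
recording site.

`fit_lambda()` fits `dE ~ A * (f*g)(0; b, lambda)` by least squares; the
amplitude A (mV) is conditionally linear and profiled exactly, leaving a
one-dimensional minimization in `lambda`. The mean squared error is
computed on the amplitude-normalized scale and fits with MSE above 0.3
(configurable) are excluded — reproducing the published numeric threshold
while avoiding its unit ambiguity.

A note on precision: with eight illumination sizes, a jointly fitted
amplitude and additive noise of 5% of the maximal response, the
Cramér–Rao bound puts the per-replicate relative error of `lambda` at
about 5–8% for any single-sided design — the estimator is essentially
unbiased (the median recovered `lambda` is within a few percent of
truth), but individual replicates scatter at the information limit. The
recovery tests therefore check the median estimate.

`fit_power_relation()` fits `y = a x^b` by nonlinear least squares
(log-log start, conditionally linear amplitude) and profiles each
parameter with an F-statistic comparison at the 99% level to obtain
confidence intervals; on exact data the intervals collapse to the
estimate. It serves the square-root relation `lambda ~ sqrt(R_m)`
expected from cable theory when coupling is fixed and membrane resistance
varies.

## Synthetic data

All generators are pure functions of their configuration and seed, and
attach a `truth` record sufficient to compute every downstream expected
value. Defaults emulate the recording conditions: 10-kHz sampling, 275-ms
cycles, additive white Gaussian noise of 0.3 mV (typical sharp-electrode
noise; the pipeline tests also use 0.5 mV), 50 cycles for averaging, and
optional linear offset drift. The passive surrogate is a single-
compartment RC membrane (default 60 megohms, 100 pF) driven by a step
current or by the calibrated ChR2 waveform; its 50-ms default pulse is
long relative to the membrane time constant so the response approaches
the Ohm's-law plateau. What the generators do not emulate: 50-Hz
interference and other colored noise, electrode impalement artifacts,
motion, multi-cell signals, or tissue-level coupling — passing tests
demonstrate correctness of the algorithms under the stated noise model,
not robustness to every artifact of real recordings.

## Numerical choices

* Stiff integration with `deSolve::lsoda`: relative tolerance 1e-6 and
  per-state absolute tolerances for the coupled cell model, 1e-8/1e-12
  for the standalone photocycle; square light pulses are handled by
  segmenting the integration at pulse edges; output is resampled to the
  10-kHz recording grid.
* Root finding: bisection/`uniroot` with bracket expansion; the leak
  calibration tolerates unstable (non-evaluable) upper brackets by
  treating them as overshoot; the threshold search tolerates the
  metastable depolarized regime because the upward scan terminates at the
  first capturing intensity, far below it.
* The trace-driven photocurrent computation (`current_along_trace()`)
  conditions the photocycle with 15 s of pre-pacing on the cycle without
  the probe pulse before simulating the cycle of interest, so
  desensitization is reflected in the reported currents.
* Problem sizes used by the test suite and acceptance script: 10
  conditioning cycles per measurement, 100-replicate statistical suites,
  50-cycle synthetic recordings — chosen as the smallest sizes at which
  the measured quantities are stable to well within their tolerances.

## Limitations

* Single-cell only: no cable or monodomain tissue simulation, no
  transmural light attenuation, no fiber-rotation anisotropy; the space
  constant enters only through the convolution model of the measurement,
  not through a coupled tissue simulation.
* The drug tables are qualitative signatures, not measured IC50 sets.
* The rectification exponent calibration reflects this implementation of
  the ionic model; small implementation differences (solver tolerances,
  stimulus placement) shift the calibrated value by a few percent.
* The metastable depolarized state bounds the leak range (~8 mV of
  diastolic depolarization under the default protocol); stronger
  depolarizations are reported as unstable rather than measured.
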