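---
title: "Three kinetic formalisms for the Kv1.1 potassium channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three kinetic formalisms for the Kv1.1 potassium channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kv11sim)
```

# Scope

kv11sim implements three published descriptions of the macroscopic current
carried by the shaker-related voltage-gated potassium channel Kv1.1
(KCNA1) at physiological temperature (35 degC), together with the
patch-clamp voltage protocols used to characterize it and the feature
extraction used to compare them:

* a **Hodgkin-Huxley (HH) model** with one activation gate m and one
  inactivation gate h, both relaxing first-order toward voltage-dependent
  steady states, with Q10-style temperature scaling;
* an **8-state continuous-time Markov model** (four closed states, one
  open state, two slow-inactivated states, one fast-inactivated state)
  whose voltage-dependent rates follow single-exponential laws;
* a **Hammerstein-Wiener (HW) cascade** — a static piecewise-linear input
  map, a third-order linear transfer function, and a static
  piecewise-linear output map — the "system theory-based" description that
  treats the channel as an input/output system without biophysical state.

All three are parameterized with the published Kv1.1 constants, and every
number the package reproduces is computed by simulation at run time, never
hard-coded.

# Voltage protocols

`preset_protocol()` builds the four standard stimulation protocols:
activation (500 ms steps, -90 to +80 mV in 10 mV increments, from a
-80 mV holding), deactivation (300 ms activating pulse at +70 mV followed
by 300 ms tails from -80 to +30 mV), inactivation (1500 ms conditioning
pulses from -40 to +70 mV followed by a +30 mV test pulse), and a ramp
protocol with four triangular excursions (400/200/100/50 ms) separated by
400 ms recovery holds.

Two conventions matter downstream:

* **Half-open segment edges.** The sample falling exactly on a segment
  transition belongs to the *new* segment. Feature windows therefore
  exclude their right boundary; including it would contaminate, e.g., a
  conditioning-pulse fit with the first test-pulse sample.
* **Analysis range.** The activation preset carries the full measured
  range (to +80 mV), but all published analyses use sweeps up to +70 mV
  and normalize conductances at the +70 mV step, so feature extraction
  defaults to `subset_protocol(p, seq(-90, 70, 10))`.

The ramp excursion endpoints are only shown graphically in the source
material; the preset defaults to -90 to +50 mV excursions and both
endpoints are arguments. Because of this ambiguity the ramp-derived
feature (`v_max_cond`) is reported but not held to a published value.

The default sampling interval is `dt = 0.05` ms (20 kHz), which resolves
the fastest gating time constants in the models (~0.1 ms at depolarized
voltages) with at least two samples.

# The Hodgkin-Huxley model

The current is `I = g * m^p * h^q * (V - E_K)` with `p = q = 1`,
`E_K = -65` mV, and `g = 1` because the published model was fitted to
normalized currents (an absolute scale can be set via `g_bar`). The
steady states are

* `m_inf(V) = 1/(1 + exp(-(V + 14.16)/10.15))` (the slope is written
  positive so that activation increases with depolarization), and
* `h_inf(V) = (1 - A) + A/(1 + exp((V + 31.0)/5.256))` with
  `A = 0.032*T - 0.365`; at 35 degC `A = 0.755`, i.e. 24.5% of channels
  never inactivate at strong depolarization.

The inactivation time constant is a single Boltzmann divided by
`2.7^((T - 25)/10)`; the activation time constant blends two sigmoidal
components through a switching sigmoid at -46.7 mV and is divided by a
voltage- and temperature-dependent factor
`(7.54 e^(-V/379.7) e^(-T/35.66))^((T-25)/10)` (the exponent notation in
the source is ambiguous; it is read as (T-25)/10 by analogy with the
inactivation law, which is self-consistent at 35 degC).

**Integration.** Within any span of constant voltage the gates relax
exactly as `x(t) = x_inf - (x_inf - x0) exp(-t/tau)`, so the default
integrator applies that update sample by sample: it is exact for step
protocols at any `dt` and a piecewise-constant approximation on ramps. A
stiff adaptive solver (`method = "ode"`) is kept as an independent
cross-check; both agree to 1e-6 on step protocols (tested). Gates are
initialized at the steady state of the first sample's voltage, mimicking
the experimental holding period.

**A known discrepancy.** The published feature table reports activation
time constants of ~0.24-0.30 ms that are nearly voltage-independent, and
an activation conductance fit of V1/2 = -14.94 mV, k = 9.913 mV. The
printed activation-time-constant equations, however, evaluate to
0.46-6.8 ms over the same voltage range, and a faithful simulation of the
printed equations yields V1/2 = -13.78 mV, k = 10.97 mV — a shift
explained entirely by how much the h gate decays before the current peaks
at each voltage (slower activation at low voltages means later peaks).
No fit window, amplitude convention, or blanking choice reconciles the
two (we grid-searched all sub-windows of -90..+70 mV and both free- and
fixed-amplitude fits); substituting a constant ~0.28 ms activation time
constant reproduces the published pair almost exactly. We conclude the
published simulations used faster activation kinetics than the printed
equations and we deliberately implement the printed equations. The
inactivation-side features are unaffected: the simulated inactivation
time constants (32.20 ms at +70 mV, 179.7 ms at -40 mV) and the
steady-state inactivation fit (-29.15 mV, 3.86 mV) match the published
values to better than 1%.

**Steady-state inactivation fit convention.** Fitting the published
values to better than 1% requires fixing the hyperpolarized plateau of
the availability Boltzmann at 1 (the curve is normalized to its maximum
before fitting); the free four-parameter fit instead recovers the
model's underlying `h_inf` parameters (-31.0 mV, 5.26 mV). Both are
available (`fit_boltzmann_inactivation(fix_top = )`); the fixed-top
variant is the default.

# The 8-state Markov model

States `C1-C2-C3-C4` (closed), `O` (open), `IC1`, `IC2` (slow
inactivation), `IN` (fast inactivation). Voltage-dependent rates follow
`r1 * exp(+/- V/r2)` with the sensitivities `r2` in volts (command
voltages in mV are divided by 1000); `c, d, k, m, x, y` are
voltage-independent. The macroscopic current is
`I = g * N_c * P_O * (V - E_K)` with `g = 8.7` pS and per-protocol channel
counts (`kv11_channel_counts`: 3088 activation, 2588 deactivation and
inactivation, 2388 ramp).

**The scheme is data.** The published state diagram is a figure, not a
table, so the exact edge set cannot be transcribed mechanically. Two
constraints pin most of it: the published master equation for the open
state,

    dP_O/dt = P_C4 c + P_IC2 y + P_IN eta - P_O (d + lambda + 2x),

which `validate_scheme()` enforces term by term on every scheme the
package accepts, and the published text (a four-step closed chain driven
by alpha/beta, slow inactivation reachable from both the closed and the
open side, a direct IC2-IN cross-link). The remaining freedom —
multiplicities on the closed chain, which closed state couples to IC1,
which rate pair sits on each inactivation edge — was resolved by
simulating candidate transcriptions and keeping the one that reproduces
the published *simulated* feature column (activation midpoint and slope,
deactivation tail time constants, steady-state inactivation midpoint and
slope, inactivation time constant at -40 mV). The shipped default:

* chain `C1 -> C2 -> C3 -> C4` at `3a / 2a / a` against `b / 2b / 3b`
  (the subunit-style statistical multiplicities);
* `C4 <-> O` via `c`/`d`;
* `C4 -> IC1` at `eps(V)`, recovery `IC1 -> C4` at `sigma(V)` — with the
  opposite assignment the inactivated pool leaks back at ~58/s and the
  model cannot inactivate below an open probability of ~0.7,
  contradicting the published occupancy and current plots;
* `IC1 <-> IC2` via `k`/`m`; `O -> IC2` at `2x`, back at `y`;
* `O <-> IN` via `lambda`/`eta`; cross-link `IC2 -> IN` at `x`,
  `IN -> IC2` at `y`.

With it the simulated features are: activation -22.59 mV / 12.08 mV
(published -22.64 / 11.82), steady-state inactivation -28.62 mV / 5.18 mV
(published -28.95 / 5.04), inactivation time constant at -40 mV 243 ms
(published 239.5), deactivation tails within ~10% across -80..-30 mV. The
one systematic residual is the inactivation time constant at depolarized
voltages (~104 ms vs published ~68 ms), so the transcription of the
inactivation wiring is close but probably not exact; users can supply a
corrected edge list as plain data (`kv11_scheme(edges = )`) without
touching code.

**Numerics.** Deterministic simulation advances the master equation with
the exact matrix-exponential solution per constant-voltage span, via one
eigen-decomposition per voltage level (with a conditioning check and a
repeated-`expm` fallback), and a stiff ODE path as cross-check; occupancy
is conserved to 1e-8 and the two propagators agree to 1e-6 (tested).
Stationary initialization takes the null-space eigenvector of the
generator at the holding voltage, refined by long-time propagation if the
eigen-solve is unreliable. The stochastic simulator evolves each channel
with exact per-sample transition matrices `expm(Q dt)` — never the
first-order `I + Q dt` approximation, so probability bounds hold at any
`dt` — and is bit-reproducible given a seed; with 2000 channels the open
fraction stays within three binomial standard errors of the master
equation (tested).

# The Hammerstein-Wiener model

The published cascade is `v' = f(v)`, a third-order transfer function
`G(s)` with printed coefficients (denominator `s^3 + 4321 s^2 +
4.104e8 s + 1.596e9`, numerator `-1.269e4 s^2 - 1.754e8 s - 6.268e8`),
and `i = g(i')`, where `f` and `g` are gain-switched piecewise-linear
maps with slopes (1.2, 0.2, 0.1) and (-0.3, -0.1, -0.01). Three points:

* The printed nonlinearities switch the *gain* by input region; they are
  not offset-matched, so the maps are discontinuous at the breakpoints.
  This is implemented literally (region switching on the input's value,
  right-closed at a breakpoint), with an optional `continuous` mode.
* The breakpoint *positions* are not printed in the main text. The
  defaults in `kv11_hw_model()` are placeholders near the operating-range
  boundaries of the deviation signals and are clearly documented as
  non-published configuration.
* A transfer function assumes zero initial conditions, so the linear
  block operates on deviations from the holding level (the first sample
  of each sweep), not raw voltages.

Simulation uses a zero-order-hold discretization of the controllable
canonical state-space realization at the stimulus `dt`; against the
partial-fraction closed-form step response it is accurate to 1e-6
relative (tested), and the printed denominator is verified strictly
Hurwitz-stable (all three poles in the left half-plane; DC gain -0.393).

# Feature extraction

`conductance_curve()` takes the peak current per sweep inside the test
segment — excluding a 0.5 ms blanking window after the step edge, which
in recorded data removes capacitive spikes and in simulated data is
inert — converts to conductance with `G = I_peak/(V - E_K)`, and
normalizes at the +70 mV sweep. `fit_boltzmann_activation()` fits the
standard rising Boltzmann `1/(1 + exp((V1/2 - V)/k))` (the printed form
omits the "1+"; the standard form is implemented). Decay fits
(`fit_tau_decay()`) run from the in-window peak to the window end, with
the offset initialized from the final 5% of the window and the rate from
a log-linear regression before Levenberg-Marquardt refinement, plus a
coarse multi-start on failure. Inactivation time constants are fitted on
the *conditioning* pulse: the per-voltage published values match the
closed-form `tau_h` at the conditioning voltage, which identifies the
pulse actually analyzed. `rmse_traces()` averages per-sweep RMSE, with a
normalized mode that scales both trace sets by their +70 mV sweep maximum
(or the global maximum for single-sweep ramp data). `feature_table()`
assembles the full per-model comparison.

Activation-time-constant fits (`fit_tau_activation()`, rising
`1 - exp(-t/tau)` between stimulus onset and peak) are provided and
validated by parameter recovery on synthetic rises, but their published
per-voltage values are not reproduction targets for the reasons above.

# Identification

`fit_hw_pem()` minimizes the RMS simulation error of the cascade. The
search is separable: for a candidate stable denominator (positive
coefficients, optimized on a log scale by Nelder-Mead from several
seeded restarts) the numerator follows by ordinary least squares on the
states of `1/D(s)`; with identity nonlinearities this is exactly linear
output-error estimation, and a known 3-pole/2-zero cascade is recovered
to an output RMSE below 1e-6 noise-free (tested). The cascade has a
three-way scale ambiguity (input gain x transfer-function gain x output
gain); the first input slope is fixed at 1.

`fit_hmm_pso()` is a canonical constriction-coefficient particle swarm
(inertia 0.729, cognitive/social 1.49445, reflecting bounds, non-finite
particles re-seeded) over a named subset of rate parameters, minimizing
summed per-protocol RMSE. The published work gives no swarm
hyperparameters, so the canonical constants are used; the full
20-parameter fit reported there (30 h on 12 cores) is out of scope by
design — tests recover 2 free parameters from noise-free data within 5%
in seconds. `estimate_channel_count()` is the 1-D least-squares scale
between the per-channel simulation and an absolute-current recording,
rounded to the nearest integer.

# Synthetic recordings

`generate_cell()` emulates a whole-cell measurement: model current plus
i.i.d. Gaussian noise and biphasic capacitive spikes at every step edge
(exponential decay, time constant 0.3 ms, amplitude proportional to the
step size, sign following the step direction), with seal resistance,
series resistance, offset voltage, and membrane capacitance metadata.
`generate_population()` draws channel counts lognormally (the
cell-to-cell current magnitude varies considerably in real recordings)
and `qc_filter()` applies the published exclusion rule (seal resistance
below 300 MOhm) plus an optional baseline-noise threshold standing in
for the manual "high noise" exclusions, which have no published formula.

What the generator does *not* emulate: series-resistance voltage errors,
amplifier filtering, leak currents, liquid-junction offsets, or seal
instability over time. Passing the end-to-end recovery tests therefore
shows the pipeline is unbiased under idealized noise and artifacts, not
that it is robust to every pathology of real recordings.

Default population conditions: channel-count median 2588 with lognormal
sigma 0.3 (matching the published per-protocol counts' scale and the
reported cell-to-cell variability), noise 0.05 nA, seal resistances
lognormal around 600 MOhm so that a realistic fraction fails the 300 MOhm
rule.

# Reproduction status

Computed by `scripts/acceptance.R` (and asserted by the test suite at
~2% for deterministic quantities):

* HH inactivation time constants, steady-state inactivation midpoint and
  slope: reproduce the published values to <1%.
* Markov activation midpoint: <0.3%; activation slope: 2.2% (the
  figure-transcription residual discussed above).
* HH activation midpoint/slope: intentionally *not* reproduced
  (-13.78/10.97 vs published -14.94/9.913); the package simulates the
  printed equations, which the published simulation evidently did not.
* Ramp `v_max_cond` and activation time constants: reported, not held to
  published values (ramp endpoint and fit-window ambiguities).

# Known limitations

* The Markov scheme is a best-effort transcription of a figure;
  inactivation kinetics at depolarized voltages run ~50% slow.
* The HW breakpoints are placeholders; quantitative HW feature values
  depend on them.
* PEM supports piecewise-linear nonlinearities only (one or more
  regions); sigmoid/wavelet/dead-zone variants are out of scope.
* Ramp simulation treats voltage as piecewise-constant at `dt`
  resolution (exact integrators per sample); at the default 20 kHz this
  is far below any other error source.
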