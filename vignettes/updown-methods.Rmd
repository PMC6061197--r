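---
title: "Models and methods: spontaneous up/down dynamics in noisy spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: spontaneous up/down dynamics in noisy spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(updownnet)
```

# The system

`updownnet` simulates and analyses sparse random networks of two-variable
spiking neurons whose synapses carry both spike-triggered conductance jumps
and a continuous stochastic component ("synaptic noise", the molecular-level
fluctuation of neurotransmitter release that produces miniature postsynaptic
potentials). Networks of this kind self-organize into a small set of
collective states — asynchronous irregular firing, rhythmic alternation of
depolarized (up) and hyperpolarized (down) phases, and, at intermediate
noise, *intermittent* switching between an oscillatory active regime and a
near-rest quiescent regime. The package provides every layer of that study
as reusable, tested code:

* single-neuron dynamics (Izhikevich quadratic and AdEx exponential
  variants) with phase-plane tools;
* the conductance-based synapse with Ornstein-Uhlenbeck (OU) noise;
* a stochastic-Heun network integrator (compiled core);
* population measures: firing rate, spike/voltage power spectra, spectral
  entropy, phase-locking value (PLV), mean-input balance estimate, `1/f^n`
  fits;
* threshold-based segmentation into up/down/rest states and
  active/quiescent periods with duration statistics;
* synthetic fixtures with known structure, so every measure is testable
  without the simulator;
* experiment drivers for noise-versus-coupling state diagrams and
  duration-versus-noise scans.

# Neuron models

Each neuron has a voltage `v` (mV) and a recovery variable `u` obeying

    v' = 0.04 v^2 + 5 v + 140 - u + I(t)
    u' = a (b v - u)

with a fire-and-reset rule: when `v` reaches the cutoff `v_peak = 30` mV,
`v -> c` and `u -> u + d`. Four electrophysiological classes are bundled
(`neuron_params()`): regular-spiking (RS) and chattering (CH) excitatory
cells, fast-spiking (FS) and low-threshold-spiking (LTS) inhibitory cells.
They share the voltage-equation constants and differ only in `(a, b, c, d)`.
Units follow the dimensionless convention of this model family: `v` in mV,
time in ms, currents and `u` unitless. The recovery variable is the slow
negative feedback that terminates up states: every spike adds `d`, and a
large accumulated `u` pushes the neuron inside the parabola of the voltage
nullcline, hyperpolarizing it.

Two closed forms organize all excitability statements
(`critical_currents()`): the rest state disappears at the saddle-node
current `I_sn = (beta - b)^2 / (4 alpha) - gamma` and already loses
stability at the Andronov-Hopf current
`I_H = ((beta - b)^2 - (a - b)^2)/(4 alpha) - gamma` (subcritical because
`b > a` for all four classes). `b` is the only class parameter entering
`I_sn`, so the LTS class (`b = 0.25`, `I_sn ~ 1.02`) ignites at a four times
weaker input than the `b = 0.2` classes (`I_sn = 4`) — the single fact that
shapes most of the network phenomenology below.

The AdEx variant replaces the quadratic by a leak plus exponential term with
slope factor 30 mV, threshold −65 mV, unit leak conductance, leak reversal
tied to the reset voltage, and a constant offset −46 chosen so that the
nullclines resemble the quadratic model's. Solving the AdEx rest equation
numerically places the RS rest near −74 mV, about 4 mV below the quadratic
model's −70 mV; the two models' nullclines are similar in shape but not
within 1 mV of each other, so the package's proximity test uses a 5 mV
tolerance.

# Synapses and noise

Each neuron carries one excitatory and one inhibitory conductance with
reversal potentials 0 / −80 mV and decay constants 5 / 6 ms. A presynaptic
spike adds the increment `g_ex` (default 0.15) or `g_in` (default 1) to the
corresponding conductance of all its targets. Between spikes the
conductance follows the OU equation `dG = -G/tau dt + sqrt(2 D n) dW`,
where `n` is that neuron's in-degree of the matching kind: more inputs mean
proportionally more variance, making `(D, 2n)` statistically equivalent to
`(2D, n)`. The stationary variance of the unreflected process is
`D n tau` (`ou_stationary_stats()`), the reference value for all noise
checks. Conductances are reflected at zero — negative conductances are
unphysical — which shifts the mean of the reflected process slightly upward;
the reflection is applied in network runs as well as for isolated neurons
(configurable in the low-level core, on by default).

# Network and integration

`build_network()` draws a directed Erdos-Renyi graph (`N = 2^10`,
`p = 0.01` by default, so the mean in-degree is about 10; no self-loops),
assigns classes by composition with deterministic counts and a seeded
shuffle, and tabulates the per-neuron in-degrees that scale the noise.
Excitatory and inhibitory subpopulations default to the 4:1 cortical
proportion.

`simulate_network()` advances the full system with the stochastic Heun
(predictor-corrector) scheme; the additive conductance noise reuses the
same Wiener increment in both stages, which is the standard treatment for
additive noise (Ito and Stratonovich coincide). Design choices worth
stating explicitly:

* `dt = 0.05` ms by default. The quadratic voltage equation stiffens near
  threshold; a convergence test (halving `dt` changes the time-averaged
  rate of a fixed noisy run by less than 5%) guards the choice.
* Spikes are detected at the end of the corrector stage; recorded traces
  clamp `v` at `v_peak` (the quadratic blows up within a step otherwise),
  then the reset applies.
* Conductance jumps from a spike are delivered to the targets at the next
  integration step — an effectively zero transmission delay, as no delays
  appear in the model.
* Initial conditions are the per-class rest states with zero conductances,
  so with `D = 0` and no stimulus the network is exactly at a fixed point
  and stays silent; activity must be seeded by a stimulation protocol
  (`stim_protocol()`: amplitudes 10–20, durations 50–300 ms, fractions 1
  down to 1/16) or by noise.
* Traces are recorded every 1 ms by default (the rate-measure bin);
  full-resolution per-neuron recording is available through
  `record_interval` and `record_ids`.
* The compiled core uses its own explicitly seeded RNG, so a simulation is
  reproducible from its `seed` argument regardless of R's RNG state.

# Measures

**Firing rate.** `firing_rate()` bins the raster at 1 ms and reports
spikes per neuron per second (Hz).

**Spectra.** `power_spectrum()` is the one-sided periodogram `|FFT|^2/T`.
Spike trains enter as 1-ms binned counts (`kind = "spikes"`; the
high-frequency plateau of a Poisson train then equals its rate, in 1/s);
sampled signals such as voltages use `kind = "series"` (mV^2/Hz). The
mean is removed by default so the DC bin is empty; this matters because the
20-point moving average (`moving_average()`) used before peak-reading and
`1/f^n` fitting would otherwise smear the enormous DC component into the
first twenty bins and masquerade as low-frequency power. Peaks are read
ignoring the zeroth bin.

**Spectral entropy.** `spectral_entropy()` computes the normalized Shannon
entropy of the rate power spectrum on exactly `N_b = 1000` one-sided bins:
records longer than `2 N_b` samples have their raw periodogram bins
averaged into 1000 equal groups (which also tames the chi-squared scatter
of the raw periodogram); shorter records are zero-padded. `H_s = 1` for
broadband (white) rate fluctuations, `H_s = 0` for a single-frequency
oscillation. Zero-power bins contribute zero.

**PLV.** `plv()` draws `K = 60` random pairs of spike trains (saturation
in `K` sets in around 50), bins each at 1 ms over a 2000-ms window, takes
instantaneous phases from the analytic signal, and averages the modulus of
the time-averaged phase-difference phasor. The per-pair sum is normalized
by the number of time samples so the value lies in `[0, 1]`. One deliberate
choice: the binned train is *not* mean-subtracted before the Hilbert
transform. For sparse trains the subtracted mean leaves a constant negative
offset between spikes that dominates the analytic signal and pins the phase
near pi; independent irregular trains then appear spuriously locked (null
level ~0.4). Without the offset the real part is exactly zero between
spikes, phases decorrelate within a few samples, the null level falls to
the expected `O(1/sqrt(T))`, and identical trains still give exactly 1.
The mirror-image caveat applies to dense trains (rates approaching one
spike per bin), where the un-subtracted signal is itself nearly constant
and pins the phase near zero; for high-rate regimes the `demean = TRUE`
variant is the meaningful one, and the package's own high-rate ordering
tests use it. Neither construction is uniformly valid across rate regimes
— a genuine ambiguity of Hilbert phases for point processes — so both are
exposed and documented. Phases use no additional smoothing.

**Balance.** `balance_estimate()` evaluates the mean-field input estimate
`g_ex C_ex nu_ex tau_ex (E_ex - <v>) - g_in C_in nu_in tau_in (E_in - <v>)`
exactly as written; since `E_in < <v>` in the regimes of interest, the
printed minus sign makes the inhibitory term contribute positive current,
so a documented `sign_convention = "additive"` switch provides the variant
in which inhibition hyperpolarizes. The familiar LIF-style conclusion —
equal rates and taus and a 4:1 input ratio balance at `g_in/g_ex = 4` —
holds only under the additive convention.

# State segmentation

`label_bins()` classifies each 1-ms bin from two signals, the network-mean
voltage and the network rate:

* **up**: mean voltage above the rest band *and* rate above 20% of its
  window reference (the window-average rate by default; the window maximum
  is available — the literal "below its maximum by at least 20%" reading of
  the quiescence criterion would label near-peak activity quiescent, so the
  average-based reading is the default);
* **down**: mean voltage within 5 mV of −80 mV (and below the rest band);
* **rest**: everything else — in practice, voltage within 3 mV of the
  composition-weighted resting voltage with near-zero rate.

`segment_periods()` merges runs of up/down alternation into **active**
periods and rest runs into **quiescent** periods, absorbing runs shorter
than `min_gap = 20` ms (hysteresis against single-bin flicker). All
thresholds are recorded in the outputs. `duration_stats()` summarises
interval durations with mean, SD, SE, histogram, 3-SD outlier flags and a
log-survival linearity diagnostic for exponential shape.

These voltage bands are the package's own quantification of qualitative
anchors ("close to −80 mV", "close to the resting state"); they are
deliberately configurable. Two consequences are worth knowing. First, at
strong noise the collective voltage excursions shrink (waves of activity
merge), so hyperpolarized dips reach the down band less often and
active periods fragment; segment statistics at `D` above roughly
`3 x 10^-5` describe a low-amplitude oscillatory regime rather than clean
up/down switching. Second, the up/down sub-state durations react to noise
(both shorten), whereas replacing LTS by FS inhibition lengthens down
states at equal noise — the composition effect the duration tests assert.

# Synthetic fixtures

The `make_*` generators produce data with known ground truth so the
measures and the classifier can be validated independently of the
simulator: homogeneous Poisson rasters (maximal spectral entropy, null
PLV), jittered periodic rasters (spectral concentration at the burst
frequency, entropy rising monotonically with jitter), and two- or
three-level voltage traces with exponentially distributed dwell times and
a consistent rate series (classifier parameter recovery; the exponential
dwell choice mirrors the exponential-like duration histograms of the
simulated networks). All fixtures are bit-exact functions of their
parameters and seed.

# Experiment drivers

`run_sweep()` maps `(g_in/g_ex, D)` cells (linear ratio in `[0.5, 7]`,
log-spaced `D` in `[1e-6, 1e-2]`) to `(H_s, PLV)` with one simulation per
cell, a 500-ms transient discard, and a pure-function labeller
(`classify_state()`): oscillatory if `H_s < 0.5`, synchronous if
`PLV > 0.5`, a transition band of half-width 0.1 around both thresholds.
The thresholds are not part of the model — the qualitative diagram in the
source material is schematic — so they are explicit arguments, and
relabelling does not require re-simulation. `duration_vs_noise()` scans
noise intensities and compositions and tabulates mean durations per state
kind. Default resolutions are desk-scale (a 12 x 12 grid rather than the
full-resolution diagram; scans of tens of seconds rather than 10-minute
records); the acceptance material below states the sizes used.

# What the reproduction does and does not show

The package's acceptance material re-runs the study's headline conditions
at desk scale: 3-to-10-second records, a 1024-neuron network, 3 seeds for
stochastic quantities, 60-second records for duration scans. Several
findings reproduce robustly: the noise boundary of the state diagram
(asynchronous irregular activity below `D ~ 5e-6` independent of coupling;
oscillatory and intermittent regimes above), the intermittent switching at
`D = 1e-5` with segment-wise spectral entropies near 0.74 (quiescent) and
0.37 (active) and a trimodal mean-voltage histogram, the ~100 ms up/down
cycle of the deterministic oscillation, the ~10 Hz spike-spectrum peak at
strong noise, the 80-ms floor of quiescent durations, and the AdEx variant
of the intermittent state.

Two weak-noise quantities do not reproduce from the printed equations and
parameters. With the stated conductance-noise process, the excitatory
ignition threshold sits several noise standard deviations above the mean
input (the isolated-neuron first-spike time at the relevant `D n` exceeds
tens of seconds), so excitatory cells are essentially silent at
`D = 2.5e-6` and the reported ~1 Hz excitatory rate — and with it part of
the reported spectral-entropy depression — is not attainable in this
implementation; the inhibitory rate (~8 Hz) and the position of the
diagram boundary, which pin down the noise scaling from two independent
directions, do reproduce. The PLV construction is similarly
underdetermined by its printed definition; the package's default is the
variant that satisfies the stated bounds and null behaviour (see above),
and it reads lower than the reported values in strongly oscillatory
states. Both points are design decisions of this package, documented here
rather than tuned away.

Two further desk-scale limitations. The deterministic self-sustained
"constant" state of the excitation-dominated network (low `g_in/g_ex`)
dies within a few hundred milliseconds here rather than persisting, and
its strong-noise counterpart retains a collective adaptation rhythm with
measurable phase locking instead of reading as fully asynchronous — the
left third of the qualitative state diagram is therefore not reproduced;
the noise ordering that is robust (asynchronous irregular at weak noise
turning oscillatory and more synchronous as `D` grows, at strong
inhibition) is what the tests assert. And the segment-duration trends hold
in the intermittent regime but not beyond `D ~ 3e-5` for RS+LTS networks,
where the collective voltage excursions shrink and the threshold
segmentation reads the low-amplitude oscillation as near-rest.

Finally, the fixtures emulate second-order structure (rates, spectra,
dwell-time distributions), not the full dynamics: passing fixture tests
shows the measures are correct, not that real cortical data would behave
like the model.

# Numerical notes

* Degenerate inputs are rejected with explicit errors: all-zero rate
  series (entropy undefined), spike-free PLV windows, empty voltage grids,
  zero-length segments, `D = 0` first-passage problems (the rest state is
  stable; no spike ever occurs).
* `|v| > 500` mV aborts a simulation with a diagnostic rather than
  propagating overflow.
* Ties in the segment merge are resolved by absorbing the shortest run
  first, into its left neighbour when it has one.
* The analytic signal is built by the standard FFT half-spectrum
  construction; records are used at their native length.
* Rasters round-trip through TSV bit-exactly (17 significant digits);
  traces use a plain-text directory container (CSV datasets plus a JSON
  config sidecar).
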