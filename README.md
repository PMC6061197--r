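# updownnet

Simulation and analysis of spontaneous collective activity in sparse random
networks of spiking neurons with noisy conductance-based synapses.

Cortical networks in vivo alternate between "synchronized" epochs — slow
rhythmic swings of the membrane potential between a depolarized, high-firing
**up** state and a hyperpolarized, silent **down** state — and
"desynchronized" epochs of low, irregular firing. This package re-implements,
as tested R code with a compiled integrator, a modelling study of how
synaptic noise (the molecular fluctuation behind miniature postsynaptic
potentials) turns transient up/down oscillations of a sparse spiking network
into a persistent **intermittent** state that switches spontaneously between
an oscillatory active regime and a near-rest quiescent regime.

## The model

Each of `N = 2^10` neurons follows the two-variable Izhikevich dynamics

```
v' = 0.04 v^2 + 5 v + 140 - u + I(t),      u' = a (b v - u),
v >= 30 mV  =>  v -> c,  u -> u + d,
```

with class parameters `(a, b, c, d)` for regular-spiking (RS) and chattering
(CH) excitatory cells and fast-spiking (FS) / low-threshold-spiking (LTS)
inhibitory cells (an AdEx variant is included). Directed connections exist
with probability `p = 0.01` (mean in-degree ≈ 10), excitatory:inhibitory =
4:1. The synaptic current is `I = G_ex (E_ex - v) + G_in (E_in - v)`; each
conductance decays exponentially (5 / 6 ms), jumps by `g_ex` / `g_in` at
presynaptic spikes, and is driven by Ornstein-Uhlenbeck noise
`sqrt(2 D n_j) xi(t)` whose variance scales with the neuron's in-degree
`n_j`, reflected at zero. Everything is integrated with the stochastic Heun
scheme (`dt = 0.05` ms).

Analysis follows the study's measures: the population firing rate
`r(t; 1 ms)`, spike-train and voltage periodograms, the spectral entropy
`H_s` of the rate spectrum on 1000 bins (1 = broadband, 0 = single
frequency), the phase-locking value (PLV) over 60 random spike-train pairs
(0 = asynchrony, 1 = synchrony), and a threshold segmentation of the
collective trace into up / down / rest states and active / quiescent
periods with duration statistics.

## A worked example

Build the study's mixed network (16% CH, 64% RS, 20% LTS), switch on
moderate synaptic noise, and look at the intermittent state:

```r
library(updownnet)

net <- build_network(network_config(
  N = 2^10, p = 0.01,
  exc_classes = c(RS = 0.8, CH = 0.2), inh_classes = c(LTS = 1),
  seed = 23
))
net
#> <connectivity> N=1024, 10400 edges (mean in-degree 10.16),
#>   composition: CH=164 LTS=205 RS=655

sim <- simulate_network(net, synapse_params(g_ex = 0.15, g_in = 1, D = 1e-5),
                        t_end = 10000, seed = 7)
sim
#> <sim_result> N=1024, izhikevich, t_end=10000 ms (dt=0.05), 469836 spikes, D=1e-05

seg <- segment_simulation(sim, t0 = 500)
duration_stats(seg, "active")
#> <duration_stats> active: n=47, mean=144.5 ms (sd=88.7, se=12.9)
duration_stats(seg, "quiescent")
#> <duration_stats> quiescent: n=47, mean=57.6 ms (sd=40.3, se=5.9)

rate <- firing_rate(sim$raster, sim$N, t0 = 500, t_end = 10000)
spectral_entropy(rate)$H_s
#> [1] 0.553491
plv(sim$raster, sim$N, t0 = 500, seed = 1)$plv
#> [1] 0.2121321
```

The network alternates between ~145-ms active periods (up/down oscillation
near 10 Hz) and shorter quiescent periods near the resting potential; the
intermediate spectral entropy (~0.55) reflects the mixture of oscillatory
and irregular epochs. Dropping the noise to
`D = 2.5e-6` yields the asynchronous irregular state (entropy near 1, PLV
near its sampling floor); setting `D = 0` and using `stim_protocol()` /
`run_deterministic_trials()` reproduces the purely deterministic transients.
`run_sweep()` maps the whole `(D, g_in/g_ex)` plane, and
`duration_vs_noise()` produces the duration-versus-noise curves.

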