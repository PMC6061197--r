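# Electrophysiological classes of the two-variable neuron models.
# Shared voltage-equation constants (dimensionless Izhikevich convention:
# v in mV, t in ms) and per-class (a, b, c, d).
common:
  alpha: 0.04
  beta: 5.0
  gamma: 140.0
  v_peak: 30.0
adex:
  gL: 1.0
  DeltaT: 30.0
  vT: -65.0
  offset: -46.0
classes:
  RS:  {a: 0.02, b: 0.20, c: -65.0, d: 8.0, role: excitatory}
  CH:  {a: 0.02, b: 0.20, c: -50.0, d: 2.0, role: excitatory}
  FS:  {a: 0.10, b: 0.20, c: -65.0, d: 2.0, role: inhibitory}
  LTS: {a: 0.02, b: 0.25, c: -65.0, d: 2.0, role: inhibitory}
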