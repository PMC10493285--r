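# Example ifatsim configuration.  Unknown keys are rejected; omitted keys
# take the package defaults.  Quantities carry explicit unit suffixes.
neuron:
  C_mem0: 1 pF
  C_mem1: 1 pF
  G_leak0: 50 pS
  G_leak1: 50 pS
  E_leak0: 0 V
  E_leak1: 0 V
  G_comp: 1 nS
  V_thresh: 0.5 V
  V_reset: 0 V
  t_refr: 0.1 ms
  E_exc: 1 V
  E_inh: 0 V
  tau_syn: 5 ms
  g0: 1 pS
timing:
  T_latency: 50 ns
  dt_pulse_base: 10 us
sim:
  dt: 10 us
  duration: 1 s
encoders:
  rate_unit: 31.25 Hz
  w_nom: 80
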