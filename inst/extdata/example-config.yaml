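# Example pipeline configuration: the worked parameter set with a fast
# sweep grid. All units are arbitrary but mutually consistent.
params:
  k1: 2.0    # maximal NADH-dependent proliferation rate (1/time)
  k2: 1.0    # NADH half-saturation scale (concentration)
  kd1: 1.0   # cell-cycle-dependent apoptosis rate (1/time)
  k3: 4.0    # glycolytic NADH inflow (concentration/time)
  k4: 2.0    # fold flux decrease from pyruvate-to-lactate conversion
  kd2: 1.0   # NADH flux rate to oxidative phosphorylation (1/time)
  pool_total: 1.0
seed: 1
stages: [steady, simulate, sweep, hypoxia, generate, fit]
sweep:
  ippi_values: [1.05, 1.5, 2.0, 5.0, 10.0]
  r0: 0.01
  n_r: 101
noise:
  sigma: 0.05
fit:
  n_restarts: 5
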