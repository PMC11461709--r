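# Scaled-down calibration profile: desk-scale budgets.
selection: all
model:
  model_id: 2
  p_bra: 0.038
  R: 0.00071
  v: 100
  n_steps: 200
prior:
  names: [p_bra, R, v]
  lower: [0.01, 0.0002, 20]
  upper: [0.1, 0.002, 150]
distance:
  name: wasserstein
  standardize: true
smc:
  n_particles: 256
  alpha: 0.6
  m_prime: 25
  sim_budget: 500000
  move_cap: 30
sa:
  n_base: 256
  m_replicates: 5
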