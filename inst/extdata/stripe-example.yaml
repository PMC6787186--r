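# Example run configuration: a 20-mer stretching on the deep-binding
# stripe.  Any omitted key falls back to the package defaults.
chain:
  n_beads: 20
  bond_length: 0.625
  target_lp: 1.39
  excluded_volume: true
surface:
  geometry: stripe
  delta_eps_kcal: -6.1
  stripe_width: 1.8
  smoothing: 0.3
scenario:
  name: stripe_confinement
  n_steps: 100000
  sample_every: 100
  discard_frac: 0.1
  seed: 1
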