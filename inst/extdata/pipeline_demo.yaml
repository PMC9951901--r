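# End-to-end demo configuration: small sizes so the full pipeline runs in
# seconds.  All randomness flows from the single seed.
seed: 123
stages: [synth, analyze, fit, kinetics]
composition:
  phi_oil: 0.10
  ao_total: 1.0e-4
partition:
  p_wi: 93
  k_i: 1.0e+4
  noise_cv: 0.05
  method: nonlinear
droplet:
  n_oleic: 120
  n_surfactant: 20
  n_antioxidant: 8
  n_water: 1500
  core_radius: 20
  interface_thickness: 17
  n_frames: 10
  radial_law: {family: gaussian, mean: 31, sd: 3}
analysis:
  bin_width: 1
  angle_bin_width: 3
oxidation:
  aoh0: 1.0e-7
  t_max: 120
  t_step: 0.5
kinetics:
  min_segment: 3
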