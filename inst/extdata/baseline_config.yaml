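geometry:
  AL: 18.0
  EL: 19.0
  THK: 0.35
material:
  mu: 0.083
  mu_post_ratio: 1.0
iop_mmhg: 18.0
airpuff:
  peak_kpa: 15.4
  fwhm_mm: 3.35
  n_steps: 6.0
stress_free:
  iterations: 3.0
  mode: per_iop
  reference_iop: 10.0
solver: []
mesh:
  resolution: 300.0
  ns: 2.0
seed: 1
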