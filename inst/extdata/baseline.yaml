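# Baseline scenario for the floating/submerged macrophyte competition
# model.  Rate constants follow the published qualitative
# parameterisation of the model (equal mortalities; faster-growing,
# more strongly self-limited floating plant; submerged plant locking up
# 10x more nutrient per unit biomass).  The nutrient levels (N0_high,
# N0_low) and the intermediate/strong biocontrol rates are
# implementer-chosen calibration values, not published numbers: they are
# set so the six-panel grid spans the full qualitative repertoire (see
# the package vignette).
label: baseline
parameters:
  l_F: 1.0
  l_S: 1.0
  a_F: 1.0
  a_S: 0.5
  c_F0: 1.0
  c_S0: 0.5
  e_F: 1.0
  e_S: 1.0
  m_F: 0.01
  m_S: 0.1
  B: 0.0
  N0: 5.0
  F0: 1.0
  S0: 1.0
run:
  t_end: 200.0
  method: adaptive
  dt: 0.01
  rtol: 1.0e-08
  n_samples: 1000
panels:
  N0_high: 5.0
  N0_low: 2.5
  B_levels:
  - 0.0
  - 0.5
  - 2.2
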