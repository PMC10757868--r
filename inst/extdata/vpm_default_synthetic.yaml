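label: synthetic-default
beta_male: 0.6
beta_proximal: 0.5
beta_pe: 0.6
beta_log2_ddimer: 0.25
points_intercept: -1.215260576537531
points_slope: 60.0
points_threshold: 180.0
risk_threshold_1y: 0.055
baseline:
  breakpoints:
  - 12.0
  - 24.0
  hazards:
  - 0.00023
  - 0.00023
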