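# Bundled "ridge invasion" demo: synthetic east-west mountain ridge with a
# single north-south valley gap; the colony starts north-east of the ridge.
domain:
  lon: [0.0, 1.2]
  lat: [0.0, 1.2]
  buffer: 0.1
terrain:
  synthetic:
    amplitude: 1500
    ridge_lat: 0.55
    ridge_width: 0.09
    valley_lon: 0.35
    valley_width: 0.06
    noise_sd: 0
    resolution: 60
    seed: 1
mesh:
  background_size: 0.1
  roi_size: 0.07
  gradient_threshold: 2500
  gradient_passes: 1
coefficients:
  nu0: 5.0e-4
  alpha: 1.0
initial:
  center: [0.9, 0.95]
  radius: 0.15
  amplitude: 10
time:
  dt_months: 0.1
  horizon_years: 14
  stride: 10
  threshold: 1
probes:
  north: [0.6, 0.9]
  gap: [0.35, 0.55]
  south: [0.8, 0.2]
uq:
  level: 1
  n_mc: 100000
  seed: 1
  inputs:
    nu:
      family: normal
      mean: 5.0e-4
      sd: 1.2e-4
    alpha:
      family: uniform
      min: 0
      max: 2
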