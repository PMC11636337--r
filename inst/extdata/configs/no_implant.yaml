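label: no_implant
grid:
  shape:
  - 64
  - 64
  - 48
  voxel_size_mm: 3.0
target:
  center_mm:
  - 0.0
  - 0.0
  - 0.0
  radius_mm: 15.0
scene:
  water_magnitude: 1.0
  background_magnitude: 0.25
sources: []
acquisition:
  delta_te_s: 0.002
  noise_sd: 0.02
  void_magnitude_threshold: 0.1
  n_motion_phases: 16.0
  seed: 1.0
motion:
- amplitude_pp_mm: 20.0
  period_s: 4.0
  exponent: 4.0
  axis:
  - 0.0
  - 0.0
  - 1.0
  baseline_mm: 10.0
static_positions_mm:
- -10.0
- -5.0
- 0.0
- 5.0
- 10.0
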