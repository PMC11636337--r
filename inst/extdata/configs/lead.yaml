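label: lead
grid:
  shape:
  - 72
  - 72
  - 64
  voxel_size_mm: 1.0
target:
  center_mm:
  - 0.0
  - 0.0
  - 0.0
  radius_mm: 8.0
scene:
  water_magnitude: 1.0
  background_magnitude: 0.25
sources:
- type: lead
  helix:
    radius_mm: 16.0
    pitch_mm: 6.0
    n_turns: 3.0
    center_mm:
    - 0.0
    - 0.0
    - 0.0
    points_per_turn: 128.0
  per_point_strength_hz_mm3: 1500.0
  tip_strength_hz_mm3: 200000.0
  exclusion_radius_mm: 3.0
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
- amplitude_pp_mm: 2.0
  period_s: 1.0
  exponent: 4.0
  axis:
  - 1.0
  - 0.0
  - 0.0
  baseline_mm: 0.0
static_positions_mm:
- -10.0
- -6.6666667
- -3.3333333
- 0.0
- 3.3333333
- 6.6666667
- 10.0
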