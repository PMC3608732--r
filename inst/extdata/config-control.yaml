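scene:
  field_height_px: 448
  field_width_px: 448
  pixel_size: 1.5
  n_segments: 9
  peritumoral_fraction: 0.3333333
  diameter_mean: 20.0
  diameter_sd: 4.0
  tortuosity: 0.15
  calibrate_dv: yes
  seed: 1
scenario:
  name: control
  treatment_time: 130.0
  lock_duration: 600.0
  reperfused_fraction: 0.5
  stagger: 100.0
  reperfuse_rule: random
  early_reperfusion_fraction: 0.0
  early_reperfusion_delay: 60.0
  perfused_fraction_late: 0.0
kinetics:
  t0: -10.0
  tau: 74.5601921
  A: 20000.0
  k_perm: 0.0
  leakage_onset_delay: 260.0
schedule:
  series:
  - - 0.0
    - 20.0
    - 120.0
  - - 140.0
    - 20.0
    - 120.0
  - - 380.0
    - 120.0
    - 3360.0
noise:
  read_noise_sd: 4.0
  photon_scale: 0.5
  drift_per_frame:
  - 0.2
  - -0.15
  background_level: 100.0
  texture_sd: 12.0
  texture_scale_px: 12.0
  bleach_rate: 0.0
segmentation:
  opening_radius_px: 1
  min_component_px: 25
  k_sd: 3.0
readouts:
  filling_fraction: 80.0
  lock_fraction: 0.05
  leakage_k_sd: 2.0
  persistence: 2
  baseline_start: 0.0
stats:
  alpha: 0.05
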