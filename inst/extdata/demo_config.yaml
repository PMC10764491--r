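# demo study: 16 simulated subjects, 2 pre sessions + 1 post-contraction
seed: 42
output_dir: swvmap_demo
simulation:
  n_subjects: 16
  subject_base_sd_mps: 0.15
  contraction_delta_mps: 0.25
  phantom:
    base_swv: 1.6
    radial_gain: 0.4
    longitudinal_gain: 0.1
    smooth_sd: 0.05
    length_mm: 120
    radius_x_mm: 22
    radius_y_mm: 14
  protocol:
    n_swipes: 5
    frame_spacing_mm: 5
    swipe_lateral_offset_mm: 9
    pose_jitter_trans_sd_mm: 0.5
    pose_jitter_rot_sd_deg: 0.5
    noise_sd_mps: 0.1
    frame_width_mm: 50
    frame_depth_mm: 32
    pixel_spacing_mm: [2, 2]
reconstruction:
  spacing_mm: 2
parameterization:
  origin_mode: centroid
  n_slices: 6
  n_angular: 6
  n_radial: 4
statistics:
  axes: [radial, angular, longitudinal]
  alpha: 0.05
report:
  figures: true
  format: pdf
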