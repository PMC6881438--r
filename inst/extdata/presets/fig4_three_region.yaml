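# Three-region demo: V1 and M1 cortex plus hippocampal CA1, small frame
seed: 1
simulate:
  state: anesthetized
  n_cells_per_region: 6
  event_rate_hz: 0.2
  duration_s: 60
  rate_hz: 10
  frame_npix: 256
  fov_diameter_um: 200
  neuropil_amp: 0.15
  noise_sd: 0.02
  crosstalk_frac: 0.001
  motion_sd_px: 1
analyze:
  k_sigma: 3
  min_separation_s: 1
  search_radius: 5
  template_frames: 100
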