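stains:
  dab:
  - 0.269
  - 0.568
  - 0.778
  hematoxylin:
  - 0.65
  - 0.704
  - 0.286
  background_level: 255.0
nuclei:
  sigma: 1.5
  threshold: otsu
  min_nucleus_area: 30.0
  split_touching: yes
  watershed_tolerance: 1.0
membrane:
  smoothing_sigma: 1.0
  min_spot_area: 30.0
  min_border_length: 5.0
  protect_min_od: 0.1
  over_nucleus_threshold: 0.5
  min_segment_length: 10.0
  min_mean_od: 0.1
scoring:
  od_thresholds:
  - 0.15
  - 0.4
  - 0.7
  complete_threshold: 0.8
  max_radius_px: 25.0
  n_angle_bins: 24.0
  weak_complete_min: 0.1
  strong_complete_min: 0.1
  core_aggregation: pool
  pixel_size_um: .na
stats:
  ci_method: bootstrap
  n_boot: 2000.0
  conf_level: 0.95
  group_test: welch
seed: 20130930.0
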