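# Example pipeline configuration: a small two-genotype synthetic
# experiment analyzed end to end. All omitted parameters fall back to
# the defaults of synappose::default_config().
seed: 7
stages: all
simulate:
  n_cultures: 2
  scenes_per_culture: 2
  synapses_per_scene: 4
  image_size_px: [256, 256]
  pixel_size_nm: 20
  offset_mean_nm: 24
  offset_sd_nm: 17
profile:
  roi_source: truth
  window_nm: 100
  smooth_px: 5
  length_nm: 1000
  width_nm: 250
segment:
  min_area_um2: 0.4
  max_area_um2: 2
classify:
  n_sd: 3
stats:
  anova_window_nm: 200
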