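# Demo configuration: a small synthetic acquisition of a clustered
# miRNA-like scene, end to end. All values are overridable; units are nm,
# ms, photons and counts as named.
pixel_size_nm: 100
seed: 7

camera:
  offset_counts: 100
  counts_per_photon: 10
  read_noise_counts: 2

detection:
  fit_window_px: 7
  min_photons: 300
  max_precision_nm: 50
  min_sigma_nm: 50
  max_sigma_nm: 300

cluster:
  preset: results     # r = 120 nm, k = 5 ("methods" preset: r = 60 nm)

render:
  target_pixel_nm: 10
  mode: gaussian

simulation:
  layout: thomas
  n_parents: 8
  mean_offspring: 12
  cluster_sigma_nm: 40
  background_n: 20
  region_um: [5, 5]
  n_frames: 200
  p_on_per_frame: 0.02
  mean_photons: 3000
  psf_sigma_nm: 130
  background_photons_per_px: 1
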