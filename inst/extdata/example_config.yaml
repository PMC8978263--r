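# Example declarative pipeline for `pasim run`.
# A blood vessel over a muscle background, imaged at two wavelengths with a
# small linear probe, reconstructed with bandpassed envelope DAS, followed
# by linear spectral unmixing.
general:
  spacing_mm: 0.4
  wavelengths_nm: [750, 850]
  volume_extent_mm: [16, 4, 16]
  rng_seed: 42
  output_path: pasim_example.h5
device:
  detection:
    kind: linear_array
    n_elements: 32
    pitch_mm: 0.4
  illumination:
    kind: slit
    length_mm: 10
    origin_mm: [0, 0, -0.5]
  position_mm: [8, 2, 0.4]
  fov_mm: [[2, 14], [0, 4], [1, 12]]
pipeline:
  - volume_creation
  - optical
  - acoustic
  - noise
  - reconstruction
  - linear_unmixing
volume_creation:
  scene:
    - kind: elliptical_tube
      params: {start: [6, -1, 7], end: [6, 17, 7], radius_a: 1.0}
      tissue: blood
      tissue_params: {oxygenation: 0.85}
      priority: 2
    - kind: background
      tissue: muscle
optical:
  n_photons: 50000
acoustic: {}
noise:
  model: gaussian
  params: {std: 0.001}
reconstruction:
  algorithm: das
  bandpass: {low_hz: 1000, high_hz: 8000000, tukey_alpha: 0.5}
  envelope: true
linear_unmixing:
  source_field: p0
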