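# Fine-pixel photon-counting detector preset (55 um nominal pixel).
detector: lambda
geometry:
  z_ss: 23.0
  z_sd: 10.25
  p_nom: 55.0
  energy_keV: 40.0
  bandwidth_keV: 0.04
  divergence_mrad: 3.0
protocol:
  n_proj: 1800
  exposure_ms: 6.25
  angular_range_deg: 360
  off_center: true
  vertical_fov_mm: 2.0
  mean_flat_counts: 115
  energy_threshold_keV: 14
  alt_setting:           # second acquisition setting
    n_proj: 3600
    exposure_ms: 12.50
    mean_flat_counts: 230
dose:
  entrance_mGy: 23.0
retrieval:
  delta_beta: 2000
source_spot_fwhm_um: [515.0, 172.0]
inpainting: true
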