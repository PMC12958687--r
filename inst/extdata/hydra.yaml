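# Coarse-pixel photon-counting detector preset (100 um nominal pixel,
# 100% filling rate: no defect corrections needed).
detector: hydra
geometry:
  z_ss: 23.0
  z_sd: 10.70
  p_nom: 100.0
  energy_keV: 40.0
  bandwidth_keV: 0.04
  divergence_mrad: 3.0
protocol:
  n_proj: 3600
  exposure_ms: 10.00
  angular_range_deg: 360
  off_center: true
  vertical_fov_mm: 2.5
  mean_flat_counts: 400
  energy_threshold_keV: 20
dose:
  entrance_mGy: 21.6
retrieval:
  delta_beta: 2000
source_spot_fwhm_um: [515.0, 172.0]
inpainting: false
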