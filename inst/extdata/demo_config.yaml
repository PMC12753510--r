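# Demo pipeline configuration: a small seeded cohort through every stage.
# All keys are optional; omitted ones fall back to the package defaults.
cohort:
  n_ms: 4
  n_sc: 4
  seed: 1
stages:
  simulate: true
  fit_dki: true
  fit_dsc: true
  oxygen: true
  roi: true
  stats: true
dki:
  snr: 30
  metrics: [md]
  regions: [deep_nawm, cc_nawm, unspecific_lesion, ms_lesion]
dsc:
  tr: 0.8          # s
  te: 0.032        # s
  n_frames: 80
  baseline_frames: 10
  noise_sd: 0
  fit_k2: true
  aif: {t0: 8.0, r: 3.0, scale: 1.5, peak: 15.0}
oxygen:
  nawm_cbf: 22     # ml/100 ml/min, calibrates relative flow
  cmro2_target: 2.5
output:
  write_nifti: false
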