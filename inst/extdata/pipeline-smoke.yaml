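# Minimal end-to-end configuration: 16^3 phantom, 60-patient cohort.
phantom:
  grid_shape: [16, 16, 16]
  spacing: [8, 8, 8]
  motion_amplitude: 12
  motion_decay: 1.5
  noise_sd: 0
  seed: 20240601
registration:
  use_truth_field: true
ventilation:
  threshold: 1.2
dose:
  prescription: 60
  falloff_mm: 40
cohort:
  n_patients: 60
  seed: 20240601
selection:
  method: stepwise
  seed: 20240601
evaluation:
  n_boot: 50
  seed: 20240601
output:
  dir: ventidose-smoke
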