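chamber:
  pressure_atm: 1.0
  volume_l: 25.0
  area_m2: 0.0625
flux_qc:
  start_center: 421.0
  start_halfwidth: 100.0
  b_max: 1.0
  b_min: 0.0
  r_cut: 0.5
  trim_head_s: 10.0
  trim_tail_s: 10.0
  cz_window_s: 15.0
traits:
  ldmc_max: 1.0
  sla_min: 5.0
  sla_max: 500.0
  n_max: 6.4
  folded_species:
  - Festuca rubra
  - Festuca ovina
  - Festuca vivipara
  - Avenella flexuosa
  - Nardus stricta
microclimate:
  air_temperature:
  - -40.0
  - 30.0
  ground_temperature:
  - -40.0
  - 35.0
  soil_temperature:
  - 5.0
  - 20.0
  soil_moisture_min: 0.0
  moisture_soil_class: silt_loam
  moisture_coefficients:
  - 0.0
  - 1.0
processing:
  night_correction: yes
  seed: 1
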