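# Default run configuration. Densities come from the packaged synthetic
# table unless mosaic.density_table points at a subject-specific file.
seed: 1
model:
  k: 4
  tau_init: 1000
mosaic:
  # density_table: path/to/densities.csv
optics:
  enabled: false
  pupil_mm: 5.9
  age: 29
  pigmentation: medium
  wavelength_nm: 555
strategy:
  lapse_rate: 0.03
  guess_rate: 0.03
fixture:
  tau: 3465
  offset: 2.36
  noise_sd_db: 1
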