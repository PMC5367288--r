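description: >
  Bank-resident individual: a narrow shallow high-use band and sporadic,
  mildly night-biased off-bank excursions.
behavior:
  band_center: 18
  band_sd: 5
  excursion_rate_by_diel: {DAWN: 0.03, DAY: 0.02, DUSK: 0.04, NIGHT: 0.08}
  type_mix: {TRANSITORY: 0.70, EXTENDED: 0.20, DIRECTED: 0.10}
  noise_sd_depth: 0.5
  noise_sd_temp: 0.1
metadata:
  site: SW_ELEUTHERA
  tag_lat: 24.848
  tag_lon: -76.382
  programming: SR
  nominal_resolution: 2
mortality: ~
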