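description: >
  Strongly night-biased off-bank forager with a higher overall excursion
  rate and a broader dive-type mix.
behavior:
  band_center: 22
  band_sd: 6
  excursion_rate_by_diel: {DAWN: 0.08, DAY: 0.05, DUSK: 0.10, NIGHT: 0.25}
  type_mix: {TRANSITORY: 0.55, EXTENDED: 0.25, DIRECTED: 0.20}
  noise_sd_depth: 0.5
  noise_sd_temp: 0.1
metadata:
  site: BRIDGE
  tag_lat: 24.601
  tag_lon: -76.019
  programming: SR
  nominal_resolution: 2
mortality: ~
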