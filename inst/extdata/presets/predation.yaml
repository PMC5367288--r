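description: >
  Post-release mortality / tag consumption: shortly after release the tag
  sinks steadily to the seafloor, sits there for many hours, then shows
  diel vertical oscillations; temperature lags depth by several samples.
behavior:
  band_center: 18
  band_sd: 5
  excursion_rate_by_diel: {DAWN: 0.03, DAY: 0.02, DUSK: 0.04, NIGHT: 0.08}
  type_mix: {TRANSITORY: 0.70, EXTENDED: 0.20, DIRECTED: 0.10}
  noise_sd_depth: 0.5
  noise_sd_temp: 0.1
metadata:
  site: SW_ELEUTHERA
  tag_lat: 24.775
  tag_lon: -76.323
  programming: SR
  nominal_resolution: 2
mortality:
  onset_hours_after_deploy: 6
  sink_rate: 0.25
  seafloor_depth: 1035
  plateau_duration: 18
  temp_lag: 5
  oscillate: true
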