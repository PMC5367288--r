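#' Bundled simulation scenario presets
#'
#' Three scenarios ship with the package as YAML under
#' `extdata/presets/`: `"resident"` (narrow shallow band, sporadic
#' night-biased excursions), `"night_forager"` (higher, strongly night-biased
#' excursion rates) and `"predation"` (a post-release mortality trace with a
#' lagged temperature response).
#'
#' @param name Preset name.
#' @param seed RNG seed stored into the behavioural parameters.
#' @return A list: `behavior` (a [behavior_params()]), `metadata_defaults`
#'   (list of [tag_metadata()] fields), `mortality` (list of
#'   [mortality_params()] fields, or `NULL`), `description`.
#' @export
scenario_preset <- function(name = c("resident", "night_forager",
                                     "predation"), seed = 1) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "reefdive", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  beh <- y$behavior
  params <- behavior_params(
    band_center = beh$band_center,
    band_sd = beh$band_sd,
    excursion_rate_by_diel = unlist(beh$excursion_rate_by_diel),
    type_mix = unlist(beh$type_mix),
    noise_sd_depth = beh$noise_sd_depth,
    noise_sd_temp = beh$noise_sd_temp,
    seed = seed
  )
  list(behavior = params, metadata_defaults = y$metadata,
       mortality = y$mortality, description = y$description)
}

#' Simulate a full scenario tag
#'
#' Builds metadata from a preset's defaults, simulates the track, and
#' overlays the mortality signature when the preset defines one.
#'
#' @param name Preset name (see [scenario_preset()]).
#' @param tag_id Tag identifier for the simulated tag.
#' @param deploy_date Deployment date.
#' @param n_days Deployment duration in days.
#' @param seed RNG seed.
#' @param length_stl,sex Animal covariates.
#' @return A [tag_series()].
#' @export
simulate_scenario <- function(name, tag_id = toupper(name),
                              deploy_date = as.Date("2012-06-01"),
                              n_days = 30, seed = 1,
                              length_stl = 190, sex = "F") {
  pre <- scenario_preset(name, seed = seed)
  md <- pre$metadata_defaults
  deploy_date <- as.Date(deploy_date)
  metadata <- tag_metadata(
    tag_id = tag_id, site = md$site, tag_lat = md$tag_lat,
    tag_lon = md$tag_lon, length_stl = length_stl, sex = sex,
    deploy_date = deploy_date, popoff_date = deploy_date + n_days,
    programming = md$programming,
    nominal_resolution = md$nominal_resolution,
    recovered = TRUE
  )
  series <- simulate_track(pre$behavior, metadata)
  if (!is.null(pre$mortality)) {
    mp <- pre$mortality
    onset <- as.POSIXct(deploy_date, tz = "UTC") +
      mp$onset_hours_after_deploy * 3600
    series <- simulate_mortality(series, mortality_params(
      onset = onset, sink_rate = mp$sink_rate,
      seafloor_depth = mp$seafloor_depth,
      plateau_duration = mp$plateau_duration,
      temp_lag = mp$temp_lag, oscillate = isTRUE(mp$oscillate)
    ))
  }
  series
}
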