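DIEL_LEVELS <- c("DAWN", "DAY", "DUSK", "NIGHT")
SEASON_LEVELS <- c("WINTER", "SPRING", "SUMMER", "AUTUMN")
SYNODIC_MONTH_DAYS <- 29.530588
# Minimum deployment for lunar-phase modelling: two synodic months.
MOON_ELIGIBLE_DAYS <- 59

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

julian_day <- function(datetime) {
  as.numeric(datetime, units = "secs") / 86400 + 2440587.5
}

#' Sunrise and sunset times
#'
#' Computes sunrise and sunset (zenith 90.833 degrees, i.e. the standard
#' refraction-corrected solar rise/set) for a date and location using the
#' NOAA solar-position equations. Accurate to well within 3 minutes of
#' ephemeris tables at non-polar latitudes.
#'
#' @param date A `Date` vector (the local calendar date of interest).
#' @param lat,lon Decimal degrees; longitude east-positive.
#' @return A tibble with columns `date`, `sunrise`, `sunset` (POSIXct, UTC).
#' @export
#' @examples
#' solar_events(as.Date("2011-09-01"), 24.8, -76.4)
solar_events <- function(date, lat, lon) {
  if (abs(lat) >= 66.5) {
    abort("Polar latitudes (|lat| >= 66.5) are not supported.")
  }
  date <- as.Date(date)
  # Evaluate the solar ephemeris at local solar noon of each date.
  noon_guess <- as.POSIXct(date, tz = "UTC") + (12 - lon / 15) * 3600
  jd <- julian_day(noon_guess)
  jc <- (jd - 2451545) / 36525

  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eq_centre <- sin(deg2rad(m)) * (1.914602 - jc * (0.004817 + 1.4e-05 * jc)) +
    sin(deg2rad(2 * m)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * m)) * 0.000289
  true_long <- l0 + eq_centre
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc *
    (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos(deg2rad(omega))
  declin <- asin(sin(deg2rad(obliq)) * sin(deg2rad(app_long)))

  var_y <- tan(deg2rad(obliq / 2))^2
  eq_time <- 4 * rad2deg(
    var_y * sin(2 * deg2rad(l0)) -
      2 * e * sin(deg2rad(m)) +
      4 * e * var_y * sin(deg2rad(m)) * cos(2 * deg2rad(l0)) -
      0.5 * var_y^2 * sin(4 * deg2rad(l0)) -
      1.25 * e^2 * sin(2 * deg2rad(m))
  )

  cos_ha <- cos(deg2rad(90.833)) / (cos(deg2rad(lat)) * cos(declin)) -
    tan(deg2rad(lat)) * tan(declin)
  if (any(abs(cos_ha) > 1)) {
    abort("Sun does not rise/set on this date at this latitude.")
  }
  ha <- rad2deg(acos(cos_ha))

  noon_min <- 720 - 4 * lon - eq_time # minutes past UTC midnight
  midnight <- as.POSIXct(date, tz = "UTC")
  tibble(
    date = date,
    sunrise = midnight + (noon_min - 4 * ha) * 60,
    sunset = midnight + (noon_min + 4 * ha) * 60
  )
}

#' Assign diel period
#'
#' Dawn and dusk are the 2 h windows centred on sunrise and sunset; the rest
#' of daylight is DAY and everything else NIGHT. Windows are half-open on the
#' right so the four periods partition the day exactly.
#'
#' @param timestamp POSIXct vector (UTC).
#' @param sunrise,sunset POSIXct vectors (recycled) for the record's local
#'   date, as returned by [solar_events()].
#' @return A factor with levels DAWN, DAY, DUSK, NIGHT.
#' @export
assign_diel <- function(timestamp, sunrise, sunset) {
  hr <- 3600
  out <- dplyr::case_when(
    timestamp >= sunrise - hr & timestamp < sunrise + hr ~ "DAWN",
    timestamp >= sunset - hr & timestamp < sunset + hr ~ "DUSK",
    timestamp >= sunrise + hr & timestamp < sunset - hr ~ "DAY",
    .default = "NIGHT"
  )
  factor(out, levels = DIEL_LEVELS)
}

#' Lunar illuminated fraction
#'
#' Fraction of the Moon's disc illuminated at 0h UT of each date, from the
#' low-precision Meeus series for the Sun-Moon elongation and phase angle.
#' Agrees with USNO "fraction of the Moon illuminated" tables to within about
#' 0.01.
#'
#' @param date A `Date` vector.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' lunar_fraction(as.Date("2011-09-12")) # full moon
lunar_fraction <- function(date) {
  jd <- julian_day(as.POSIXct(as.Date(date), tz = "UTC"))
  t <- (jd - 2451545) / 36525
  # Mean elongation of the Moon, Sun mean anomaly, Moon mean anomaly (deg).
  d <- 297.8501921 + 445267.1114034 * t - 0.0018819 * t^2 +
    t^3 / 545868 - t^4 / 113065000
  m <- 357.5291092 + 35999.0502909 * t - 0.0001536 * t^2 + t^3 / 24490000
  mp <- 134.9633964 + 477198.8675055 * t + 0.0087414 * t^2 +
    t^3 / 69699 - t^4 / 14712000
  i <- 180 - (d %% 360) -
    6.289 * sin(deg2rad(mp)) +
    2.100 * sin(deg2rad(m)) -
    1.274 * sin(deg2rad(2 * d - mp)) -
    0.658 * sin(deg2rad(2 * d)) -
    0.214 * sin(deg2rad(2 * mp)) -
    0.110 * sin(deg2rad(d))
  (1 + cos(deg2rad(i))) / 2
}

#' Bin lunar illumination into five factor levels
#'
#' 20% increments of illuminated fraction; fraction 1 falls in the top bin.
#'
#' @param fraction Numeric in \[0, 1\].
#' @return Ordered factor with levels `"0-20%"` ... `"80-100%"`.
#' @export
moon_bin <- function(fraction) {
  stopifnot(all(fraction >= 0 & fraction <= 1, na.rm = TRUE))
  lv <- pmin(floor(fraction * 5), 4) + 1
  labels <- c("0-20%", "20-40%", "40-60%", "60-80%", "80-100%")
  factor(labels[lv], levels = labels, ordered = TRUE)
}

#' Assign meteorological season
#'
#' Northern-Hemisphere meteorological seasons: Dec–Feb WINTER, Mar–May
#' SPRING, Jun–Aug SUMMER, Sep–Nov AUTUMN.
#'
#' @param date A `Date` vector.
#' @return A factor with levels WINTER, SPRING, SUMMER, AUTUMN.
#' @export
assign_season <- function(date) {
  mo <- lubridate::month(as.Date(date))
  out <- dplyr::case_when(
    mo %in% c(12, 1, 2) ~ "WINTER",
    mo %in% 3:5 ~ "SPRING",
    mo %in% 6:8 ~ "SUMMER",
    .default = "AUTUMN"
  )
  factor(out, levels = SEASON_LEVELS)
}

#' Is a deployment long enough for lunar-phase modelling?
#'
#' Cyclic moon-phase effects need at least two full synodic months of data
#' (59 days) to be identifiable; shorter deployments are excluded from models
#' containing the moon-phase factor.
#'
#' @param series A [tag_series()].
#' @param min_days Minimum deployment duration in days (default 59).
#' @return Logical scalar.
#' @export
moon_eligible <- function(series, min_days = MOON_ELIGIBLE_DAYS) {
  dur <- as.numeric(series$metadata$popoff_date -
                      series$metadata$deploy_date)
  dur >= min_days
}

#' Annotate tag records with diel, lunar and seasonal context
#'
#' Adds, per record: the local solar date, sunrise/sunset of that date at the
#' tag's location, diel period, lunar illuminated fraction and its 5-level
#' bin, and meteorological season. Solar events use the fixed tagging
#' location unless a per-day location table is supplied (for standard-rate
#' tags with daily geolocations).
#'
#' @param series A [tag_series()].
#' @param locations Optional tibble of daily locations with columns `date`,
#'   `lat`, `lon`; days not covered fall back to the tagging location.
#' @return A tibble: the record table plus `tag_id`, `local_date`, `sunrise`,
#'   `sunset`, `diel`, `moon_fraction`, `moon_bin`, `season`.
#' @export
annotate_context <- function(series, locations = NULL) {
  r <- tidy(series)
  lon0 <- series$metadata$tag_lon
  lat0 <- series$metadata$tag_lat
  r$local_date <- as.Date(r$timestamp + lon0 / 15 * 3600)

  days <- tibble(local_date = sort(unique(r$local_date)))
  days$lat <- lat0
  days$lon <- lon0
  if (!is.null(locations)) {
    locations <- dplyr::rename(locations, local_date = "date")
    locations$local_date <- as.Date(locations$local_date)
    days <- days %>%
      left_join(locations, by = "local_date", suffix = c("", ".loc")) %>%
      mutate(lat = dplyr::coalesce(.data$lat.loc, .data$lat),
             lon = dplyr::coalesce(.data$lon.loc, .data$lon)) %>%
      select("local_date", "lat", "lon")
  }
  ev <- purrr::pmap_dfr(days, function(local_date, lat, lon) {
    se <- solar_events(local_date, lat, lon)
    tibble(local_date = local_date, sunrise = se$sunrise, sunset = se$sunset)
  })
  ev$moon_fraction <- lunar_fraction(ev$local_date)
  ev$moon_bin <- moon_bin(ev$moon_fraction)
  ev$season <- assign_season(ev$local_date)

  r <- left_join(r, ev, by = "local_date")
  r$diel <- assign_diel(r$timestamp, r$sunrise, r$sunset)
  r
}
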