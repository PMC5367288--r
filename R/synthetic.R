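# Behavioural-state track simulator. Emulates the structure the analyses
# assume: a narrow shallow high-use band per individual (bounded AR(1)),
# sporadic off-bank excursions of three morphologies arriving as an
# inhomogeneous Poisson process with diel-specific rates, depth-coupled
# temperature, and (optionally) a post-release mortality scenario with a
# lagged temperature response.

#' Lognormal parameters from a median and interquartile range
#'
#' Solves for the (meanlog, sdlog) of a lognormal whose median and IQR match
#' the given values: with quartiles q1*q3 = median^2 and q3 - q1 = iqr,
#' q3 = (iqr + sqrt(iqr^2 + 4 median^2))/2 and sdlog = log(q3/median)/z0.75.
#' Published dive-type tables report median (IQR), so this is how type shape
#' distributions are parameterised.
#'
#' @param median,iqr Positive scalars.
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @export
lnorm_from_quartiles <- function(median, iqr) {
  median <- unname(median)
  iqr <- unname(iqr)
  stopifnot(median > 0, iqr >= 0)
  q3 <- (iqr + sqrt(iqr^2 + 4 * median^2)) / 2
  c(meanlog = log(median), sdlog = log(q3 / median) / stats::qnorm(0.75))
}

#' Default dive-type shape distributions
#'
#' Per-type distributions for maximum-depth excess over the 50 m threshold,
#' boundary-to-boundary duration excess over the 4-min floor, oscillation
#' count, and mean descent/ascent rates, parameterised as median (IQR) on
#' the scale reef-shark dive-cluster tables are printed: transitory dives
#' shallow (median 60.2 m), short (6.1 min) and single-switch; extended
#' dives moderate depth (90.1 m), long (47.6 min), oscillatory and slow;
#' directed dives deep (131.5 m), fast (0.222 m/s descent) with moderate
#' switch counts.
#'
#' @return A named list of per-type shape parameter lists.
#' @export
default_type_shapes <- function() {
  # median/iqr pin the lognormal quartiles; range rows truncate the tails
  # (published cluster tables report median (IQR) and range per variable)
  list(
    TRANSITORY = list(
      max_excess = c(median = 10.2, iqr = 16.5),
      max_excess_range = c(0.1, 56.6),
      osc_min = 0, osc_lambda = 0.1, osc_max = 1,
      descent = c(median = 0.112, iqr = 0.104),
      descent_range = c(0.002, 0.477),
      ascent = c(median = 0.103, iqr = 0.080),
      ascent_range = c(0.011, 0.464)
    ),
    EXTENDED = list(
      max_excess = c(median = 40.1, iqr = 22.2),
      max_excess_range = c(0.1, 320.8),
      osc_min = 1, osc_lambda = 0.6, osc_max = 27,
      descent = c(median = 0.043, iqr = 0.034),
      descent_range = c(0.005, 0.202),
      ascent = c(median = 0.045, iqr = 0.030),
      ascent_range = c(0.003, 0.148)
    ),
    DIRECTED = list(
      max_excess = c(median = 81.5, iqr = 57.8),
      max_excess_range = c(26.7, 386.1),
      osc_min = 0, osc_lambda = 0.45, osc_max = 6,
      descent = c(median = 0.222, iqr = 0.206),
      descent_range = c(0.042, 1.187),
      ascent = c(median = 0.166, iqr = 0.096),
      ascent_range = c(0.046, 0.627)
    )
  )
}

# truncated-lognormal draw: quartiles from (median, iqr), tails cut at the
# published range by inverse-CDF sampling
rlnorm_trunc <- function(k, par, range) {
  ln <- lnorm_from_quartiles(par["median"], par["iqr"])
  lo <- stats::plnorm(range[1], ln["meanlog"], ln["sdlog"])
  hi <- stats::plnorm(range[2], ln["meanlog"], ln["sdlog"])
  stats::qlnorm(runif(k, lo, hi), ln["meanlog"], ln["sdlog"])
}

#' Behavioural simulation parameters
#'
#' @param band_center Centre of the individual's high-use depth band (m).
#' @param band_sd Stationary SD of the band occupation (m).
#' @param excursion_rate_by_diel Named vector (DAWN, DAY, DUSK, NIGHT) of
#'   excursion start rates, events per hour.
#' @param type_mix Named probability vector over TRANSITORY, EXTENDED,
#'   DIRECTED; must sum to 1.
#' @param type_shape Per-type shape distributions; see
#'   [default_type_shapes()].
#' @param season_depth_offset Named vector (m) added to `band_center` per
#'   season; negative is shallower.
#' @param sst_by_season Named vector of sea-surface temperature per season
#'   (deg C).
#' @param thermocline_slope Temperature decrease per metre of depth
#'   (deg C/m).
#' @param noise_sd_depth,noise_sd_temp Measurement noise SDs.
#' @param seed Integer RNG seed; identical seeds give bit-identical tracks.
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(band_center = 18,
                            band_sd = 5,
                            excursion_rate_by_diel = c(
                              DAWN = 0.05, DAY = 0.04,
                              DUSK = 0.06, NIGHT = 0.12),
                            type_mix = c(TRANSITORY = 0.6, EXTENDED = 0.25,
                                         DIRECTED = 0.15),
                            type_shape = default_type_shapes(),
                            season_depth_offset = c(WINTER = -4, SPRING = 0,
                                                    SUMMER = 2, AUTUMN = 2),
                            sst_by_season = c(WINTER = 25, SPRING = 27,
                                              SUMMER = 30, AUTUMN = 29),
                            thermocline_slope = 0.03,
                            noise_sd_depth = 0.5,
                            noise_sd_temp = 0.1,
                            seed = 1L) {
  stopifnot(all(excursion_rate_by_diel >= 0),
            abs(sum(type_mix) - 1) < 1e-8,
            band_sd >= 0, noise_sd_depth >= 0, noise_sd_temp >= 0)
  stopifnot(all(DIEL_LEVELS %in% names(excursion_rate_by_diel)),
            all(DIVE_TYPES %in% names(type_mix)))
  structure(list(
    band_center = band_center, band_sd = band_sd,
    excursion_rate_by_diel = excursion_rate_by_diel,
    type_mix = type_mix, type_shape = type_shape,
    season_depth_offset = season_depth_offset,
    sst_by_season = sst_by_season,
    thermocline_slope = thermocline_slope,
    noise_sd_depth = noise_sd_depth, noise_sd_temp = noise_sd_temp,
    seed = as.integer(seed)
  ), class = "behavior_params")
}

#' Mortality / tag-consumption scenario parameters
#'
#' Describes a post-release mortality trace: a steady sink from the onset to
#' the seafloor, a long plateau there, optional subsequent diel vertical
#' oscillations (a predator's behaviour, not the shark's), and a temperature
#' response lagged behind depth because an ingested tag equilibrates slowly.
#'
#' @param onset POSIXct onset of the mortality signature.
#' @param sink_rate Sink speed, m/s (> 0).
#' @param seafloor_depth Plateau depth, m.
#' @param plateau_duration Plateau length, hours.
#' @param temp_lag Temperature lag, in samples (integer >= 1).
#' @param oscillate Add post-plateau diel oscillations (400-650 m)?
#' @param sst Ambient surface temperature used for the lagged temperature
#'   model (deg C).
#' @param thermocline_slope deg C per metre.
#' @param noise_sd_depth Depth sensor noise SD at rest (m).
#' @param noise_sd_temp Temperature noise SD (deg C).
#' @return A list of class `mortality_params`.
#' @export
mortality_params <- function(onset, sink_rate = 0.25, seafloor_depth = 1035,
                             plateau_duration = 18, temp_lag = 5,
                             oscillate = TRUE, sst = 29,
                             thermocline_slope = 0.03,
                             noise_sd_depth = 0.5,
                             noise_sd_temp = 0.05) {
  if (sink_rate <= 0) abort("`sink_rate` must be positive.")
  if (temp_lag < 1) abort("`temp_lag` must be at least 1 sample.")
  structure(list(
    onset = onset, sink_rate = sink_rate,
    seafloor_depth = seafloor_depth,
    plateau_duration = plateau_duration,
    temp_lag = as.integer(temp_lag), oscillate = isTRUE(oscillate),
    sst = sst, thermocline_slope = thermocline_slope,
    noise_sd_depth = noise_sd_depth,
    noise_sd_temp = noise_sd_temp
  ), class = "mortality_params")
}

# One excursion's piecewise-linear (time s, depth m) breakpoint path:
# descent from the current baseline depth to maximum depth, an optional
# bottom hold, n oscillations, and ascent back to the baseline. The bottom
# hold is extended if needed so the time spent below the threshold exceeds
# one sampling interval — shorter shapes cannot be resolved by the sampler
# and are the "impossible shape" case.
draw_excursion_path <- function(params, d0, dt_s, threshold = 50) {
  type <- sample(DIVE_TYPES, 1, prob = params$type_mix[DIVE_TYPES])
  shp <- params$type_shape[[type]]
  maxd <- threshold + max(rlnorm_trunc(1, shp$max_excess,
                                       shp$max_excess_range), 2)
  v_d <- rlnorm_trunc(1, shp$descent, shp$descent_range)
  v_a <- rlnorm_trunc(1, shp$ascent, shp$ascent_range)
  n_osc <- min(shp$osc_min + rpois(1, shp$osc_lambda), shp$osc_max)
  amps <- runif(n_osc, 0.15, 0.4) * (maxd - threshold)

  t <- 0
  tt <- 0
  dd <- d0
  descend_t <- (maxd - d0) / v_d
  t <- t + descend_t
  tt <- c(tt, t)
  dd <- c(dd, maxd)
  # any sub-threshold dwell longer than one sampling interval is guaranteed
  # to be sampled at least once; the margin keeps single-record dives (a
  # real and common morphology) while preventing unsampleable blips
  dwell <- (maxd - threshold) / v_d + (maxd - threshold) / v_a
  osc_t <- if (n_osc > 0) sum(amps / v_a + amps / v_d) else 0
  hold <- max(0, 1.1 * dt_s - dwell - osc_t)
  if (hold > 0) {
    t <- t + hold
    tt <- c(tt, t)
    dd <- c(dd, maxd)
  }
  for (a in amps) {
    t <- t + a / v_a
    tt <- c(tt, t)
    dd <- c(dd, maxd - a)
    t <- t + a / v_d
    tt <- c(tt, t)
    dd <- c(dd, maxd)
  }
  t <- t + (maxd - d0) / v_a
  tt <- c(tt, t)
  dd <- c(dd, d0)
  list(t = tt, d = dd, total = t, type = type)
}

#' Simulate a tag track
#'
#' Generates a full deployment of depth/temperature records on a regular
#' grid at the tag's nominal resolution. Baseline depth follows a bounded
#' AR(1) (phi = 0.98) around the seasonal band centre, so the series has
#' realistic autocorrelation; off-bank excursions arrive as an inhomogeneous
#' Poisson process with the diel-specific rates (diel periods assigned with
#' the same rules the analysis uses) and follow piecewise-linear
#' descent/oscillation/ascent profiles drawn from the per-type shape
#' distributions, always crossing the 50 m threshold. Temperature is
#' `sst - thermocline_slope * depth` plus noise. Fully reproducible from
#' `params$seed`.
#'
#' @param params A [behavior_params()].
#' @param metadata A [tag_metadata()]; the deployment span must be at least
#'   one day.
#' @return A [tag_series()]. The true excursion start times are attached as
#'   attribute `excursion_log` (a tibble with `start_time`, `type`).
#' @export
simulate_track <- function(params, metadata) {
  deploy <- metadata$deploy_date
  popoff <- metadata$popoff_date
  if (as.numeric(popoff - deploy) < 1) {
    abort("Deployment span must be at least 1 day.")
  }
  res_min <- metadata$nominal_resolution
  dt_s <- res_min * 60
  # records cover [deploy 00:00, popoff 00:00): an n-day deployment at
  # resolution r yields n * 1440 / r records
  times <- seq(as.POSIXct(deploy, tz = "UTC"),
               as.POSIXct(popoff, tz = "UTC") - dt_s,
               by = dt_s)
  n <- length(times)
  set.seed(params$seed)

  local_date <- as.Date(times + metadata$tag_lon / 15 * 3600)
  days <- unique(local_date)
  se <- solar_events(days, metadata$tag_lat, metadata$tag_lon)
  di <- match(local_date, days)
  diel <- assign_diel(times, se$sunrise[di], se$sunset[di])
  season <- assign_season(local_date)

  center <- params$band_center +
    params$season_depth_offset[as.character(season)]
  phi <- 0.98
  innov_sd <- params$band_sd * sqrt(1 - phi^2)
  dev <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi,
                                  method = "recursive"))
  depth <- pmin(pmax(center + dev, 0), 49.5)

  u <- runif(n) # drawn up-front: higher rates admit a superset of starts
  p_start <- params$excursion_rate_by_diel[as.character(diel)] * res_min / 60
  cand <- which(u < p_start)
  log_start <- as.POSIXct(character(), tz = "UTC")
  log_type <- character()
  busy_until <- 0L
  for (i in cand) {
    if (i <= busy_until) next
    path <- draw_excursion_path(params, depth[i], dt_s)
    n_ev <- ceiling(path$total / dt_s)
    j <- i + seq_len(n_ev)
    j <- j[j <= n]
    if (length(j) == 0) next
    depth[j] <- stats::approx(path$t, path$d, xout = (j - i) * dt_s,
                              rule = 2)$y
    busy_until <- i + n_ev
    log_start <- c(log_start, times[i])
    log_type <- c(log_type, path$type)
  }

  depth <- pmax(depth + rnorm(n, 0, params$noise_sd_depth), 0)
  sst <- params$sst_by_season[as.character(season)]
  temperature <- sst - params$thermocline_slope * depth +
    rnorm(n, 0, params$noise_sd_temp)

  records <- tibble(timestamp = times, depth = depth,
                    temperature = temperature, delta_limited = FALSE)
  out <- tag_series(records, metadata)
  attr(out, "excursion_log") <- tibble(start_time = log_start,
                                       type = log_type)
  out
}

#' Overlay a mortality / tag-consumption signature on a track
#'
#' From the onset, depth follows a steady sink to the seafloor, a plateau of
#' the given duration, and (optionally) diel vertical oscillations between
#' roughly 400 and 650 m. Temperature from the onset is the ambient
#' (depth-implied) temperature delayed by `temp_lag` samples plus noise —
#' the signature of a tag reading a predator's gut rather than the water.
#'
#' @param series A [tag_series()] (e.g. from [simulate_track()]).
#' @param params A [mortality_params()]; `onset` must lie within the record
#'   span.
#' @return A [tag_series()] with the modified records.
#' @export
simulate_mortality <- function(series, params) {
  stopifnot(inherits(params, "mortality_params"))
  r <- series$records
  onset <- as.POSIXct(params$onset, tz = "UTC")
  if (onset < min(r$timestamp) || onset > max(r$timestamp)) {
    abort("Mortality onset lies outside the record span.")
  }
  i0 <- which(r$timestamp >= onset)[1]
  n <- nrow(r)
  t_rel <- as.numeric(difftime(r$timestamp[i0:n], onset, units = "secs"))

  d0 <- r$depth[i0]
  t_reach <- (params$seafloor_depth - d0) / params$sink_rate
  t_plateau_end <- t_reach + params$plateau_duration * 3600
  d_new <- pmin(d0 + params$sink_rate * t_rel, params$seafloor_depth)
  if (params$oscillate) {
    post <- t_rel > t_plateau_end
    dt_post <- t_rel[post] - t_plateau_end
    d_new[post] <- 400 + 125 * (1 - cos(2 * pi * dt_post / 86400))
  }
  depth <- r$depth
  depth[i0:n] <- pmax(d_new + rnorm(length(d_new), 0, params$noise_sd_depth),
                      0)

  lag <- params$temp_lag
  idx <- i0:n
  src <- pmax(idx - lag, 1)
  temp <- r$temperature
  temp[idx] <- params$sst - params$thermocline_slope * depth[src] +
    rnorm(length(idx), 0, params$noise_sd_temp)
  temp <- pmax(temp, -5)

  records <- tibble(timestamp = r$timestamp, depth = depth,
                    temperature = temp, delta_limited = r$delta_limited)
  tag_series(records, series$metadata)
}

#' Emulate Argos transmission of an archived series
#'
#' Subsamples an archived record set to the transmitted resolution and
#' removes random contiguous blocks (failed satellite passes) totalling the
#' requested dropout fraction. Deterministic per seed. The output metadata
#' carries the new nominal resolution and `recovered = FALSE`.
#'
#' @param series A [tag_series()].
#' @param out_resolution Transmitted resolution, minutes (>= native).
#' @param dropout_blocks Fraction of transmitted records lost in blocks
#'   (0 <= x < 1).
#' @param seed RNG seed.
#' @return A [tag_series()].
#' @export
emulate_transmission <- function(series, out_resolution,
                                 dropout_blocks = 0, seed = 1) {
  native <- series$metadata$nominal_resolution
  if (out_resolution < native) {
    abort("`out_resolution` must be at least the native resolution.")
  }
  if (dropout_blocks >= 1 || dropout_blocks < 0) {
    abort("`dropout_blocks` must be in [0, 1).")
  }
  step <- max(1L, round(out_resolution / native))
  idx <- seq(1L, nrow(series$records), by = step)
  set.seed(seed)
  target <- round(dropout_blocks * length(idx))
  if (target > 0) {
    keep <- rep(TRUE, length(idx))
    block <- max(1L, round(target / 5))
    tries <- 0L
    while (sum(!keep) < target && tries < 1000L) {
      need <- target - sum(!keep)
      s <- sample.int(length(idx), 1)
      e <- min(s + min(block, need) - 1L, length(idx))
      keep[s:e] <- FALSE
      tries <- tries + 1L
    }
    idx <- idx[keep]
  }
  meta <- series$metadata
  new_meta <- tag_metadata(
    tag_id = meta$tag_id, site = meta$site, tag_lat = meta$tag_lat,
    tag_lon = meta$tag_lon, length_stl = meta$length_stl, sex = meta$sex,
    deploy_date = meta$deploy_date, popoff_date = meta$popoff_date,
    programming = meta$programming,
    nominal_resolution = out_resolution, recovered = FALSE
  )
  rec <- series$records[idx, c("timestamp", "depth", "temperature",
                               "delta_limited")]
  rec$depth <- series$records$depth_raw[idx]
  tag_series(rec, new_meta)
}

#' Simulate dive metric vectors directly
#'
#' Draws per-type dive shapes (maximum-depth excess, descent/ascent speeds,
#' oscillation count) from the preset shape distributions and derives the
#' five characteristic variables from the same piecewise-linear geometry the
#' track simulator uses: duration is descent plus ascent plus oscillation
#' time (plus a boundary-record discretisation margin), and switch count is
#' `1 + 2 x oscillations`. This preserves the geometric coupling between
#' depth, duration and speed that real dives show, without simulating a
#' full track — the fast route for studying the classification stage.
#'
#' @param n Number of dives.
#' @param type_mix Named probability vector over the three types.
#' @param type_shape Shape distributions; see [default_type_shapes()].
#' @param band_center,band_sd Baseline depth the dives start from (m).
#' @param resolution Sampling resolution used for the boundary margin
#'   (minutes).
#' @param seed RNG seed.
#' @return A tibble shaped like an accepted-event table
#'   ([segment_excursions()]) with an extra `true_type` column.
#' @export
simulate_dive_metrics <- function(n,
                                  type_mix = c(TRANSITORY = 0.55,
                                               EXTENDED = 0.25,
                                               DIRECTED = 0.20),
                                  type_shape = default_type_shapes(),
                                  band_center = 18, band_sd = 5,
                                  resolution = 2,
                                  seed = 1) {
  set.seed(seed)
  types <- sample(DIVE_TYPES, n, replace = TRUE,
                  prob = type_mix[DIVE_TYPES])
  out <- purrr::map_dfr(DIVE_TYPES, function(ty) {
    k <- sum(types == ty)
    if (k == 0) return(NULL)
    shp <- type_shape[[ty]]
    excess <- pmax(rlnorm_trunc(k, shp$max_excess, shp$max_excess_range), 2)
    maxd <- 50 + excess
    v_d <- rlnorm_trunc(k, shp$descent, shp$descent_range)
    v_a <- rlnorm_trunc(k, shp$ascent, shp$ascent_range)
    n_osc <- pmin(shp$osc_min + rpois(k, shp$osc_lambda), shp$osc_max)
    d0 <- pmin(pmax(rnorm(k, band_center, band_sd), 0), 45)
    osc_amp <- runif(k, 0.15, 0.4) * excess
    osc_time <- n_osc * (osc_amp / v_a + osc_amp / v_d)
    travel <- (maxd - d0) / v_d + (maxd - d0) / v_a
    margin <- runif(k, 0, 2) * resolution * 60
    duration_s <- pmax(travel + osc_time + margin, 2 * resolution * 60)
    # measured rates jitter around the drawn segment speeds
    tibble(
      true_type = ty,
      max_depth = maxd,
      duration_min = duration_s / 60,
      switch_count = 1 + 2 * n_osc,
      mean_descent_rate = v_d * exp(rnorm(k, 0, 0.1)),
      mean_ascent_rate = v_a * exp(rnorm(k, 0, 0.1))
    )
  })
  out <- out[sample.int(nrow(out)), ]
  out %>%
    mutate(tag_id = "SIM", event_id = dplyr::row_number(),
           rejected = FALSE, reject_reason = NA_character_, .before = 1)
}

#' Simulate period-level depth summaries for model recovery studies
#'
#' Generates the individual x date x diel-period aggregation rows the mixed
#' models consume, with known fixed effects on the log scale and a known
#' individual random intercept, so estimator recovery can be measured
#' directly. Responses are generated as `exp(mu) - 1` so that the model's
#' `log(x + 1)` transformation recovers the linear predictor exactly.
#'
#' @param n_individuals,n_days Cohort dimensions.
#' @param start_date First deployment date.
#' @param effects Named list of log-scale effect sizes: `diel_day` (added
#'   for DAY rows), `site` (added for BRIDGE), `sex` (added for M), `moon`
#'   (linear in moon bin index), `season_winter` (added in WINTER).
#' @param intercept Log-scale intercept (default `log(21)`).
#' @param ind_sd Individual random-intercept SD (log scale).
#' @param resid_sd Residual SD (log scale).
#' @param response `"mean_depth"` or `"deep_count"` (counts are rounded).
#' @param seed RNG seed.
#' @return A tibble of period summaries (see [aggregate_periods()]).
#' @export
simulate_period_summaries <- function(n_individuals = 10, n_days = 120,
                                      start_date = as.Date("2012-01-01"),
                                      effects = list(diel_day = -0.3,
                                                     site = 0.3, sex = 0.3,
                                                     moon = 0,
                                                     season_winter = 0),
                                      intercept = log(21),
                                      ind_sd = 0.3, resid_sd = 0.5,
                                      response = c("mean_depth",
                                                   "deep_count"),
                                      seed = 1) {
  response <- match.arg(response)
  set.seed(seed)
  ids <- sprintf("SIM%02d", seq_len(n_individuals))
  b <- setNames(rnorm(n_individuals, 0, ind_sd), ids)
  # balanced, near-orthogonal sex and site assignment: between-individual
  # effects are estimated against the individual variance, so a balanced
  # design is what gives the recovery study its nominal power
  sex <- setNames(rep_len(SEXES, n_individuals), ids)
  site <- setNames(rep_len(rep(SITES, each = 2), n_individuals), ids)
  len <- setNames(rnorm(n_individuals, 190, 15), ids)

  grid <- tidyr::expand_grid(
    tag_id = ids,
    date = start_date + 0:(n_days - 1),
    diel = factor(DIEL_LEVELS, levels = DIEL_LEVELS)
  )
  grid <- grid %>%
    mutate(
      moon_fraction = lunar_fraction(.data$date),
      moon_bin = moon_bin(.data$moon_fraction),
      season = assign_season(.data$date),
      sex = factor(sex[.data$tag_id], levels = SEXES),
      site = factor(site[.data$tag_id], levels = SITES),
      length_stl = len[.data$tag_id]
    )
  ef <- function(x, nm) if (is.null(x[[nm]])) 0 else x[[nm]]
  mu <- intercept + b[grid$tag_id] +
    ef(effects, "diel_day") * (grid$diel == "DAY") +
    ef(effects, "site") * (grid$site == "BRIDGE") +
    ef(effects, "sex") * (grid$sex == "M") +
    ef(effects, "moon") * (as.integer(grid$moon_bin) - 3) +
    ef(effects, "season_winter") * (grid$season == "WINTER") +
    rnorm(nrow(grid), 0, resid_sd)
  value <- pmax(exp(mu) - 1, 0)
  if (response == "deep_count") {
    grid$deep_count <- round(value)
    grid$mean_depth <- NA_real_
  } else {
    grid$mean_depth <- value
    grid$deep_count <- NA_integer_
  }
  grid
}
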