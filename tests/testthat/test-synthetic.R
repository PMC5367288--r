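test_that("lognormal quartile matching is exact", {
  p <- lnorm_from_quartiles(10.2, 16.5)
  expect_equal(stats::qlnorm(0.5, p["meanlog"], p["sdlog"]), 10.2,
               ignore_attr = TRUE)
  iqr <- stats::qlnorm(0.75, p["meanlog"], p["sdlog"]) -
    stats::qlnorm(0.25, p["meanlog"], p["sdlog"])
  expect_equal(iqr, 16.5, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("tracks are reproducible from the seed and differ across seeds", {
  meta <- make_meta(tag_id = "S", days = 5)
  a <- simulate_track(behavior_params(seed = 21), meta)
  b <- simulate_track(behavior_params(seed = 21), meta)
  c <- simulate_track(behavior_params(seed = 22), meta)
  expect_identical(a$records, b$records)
  expect_false(identical(a$records$depth, c$records$depth))
  expect_false(identical(attr(a, "excursion_log")$start_time,
                         attr(c, "excursion_log")$start_time))
})

test_that("zero excursion rates keep the track on-bank", {
  p <- behavior_params(excursion_rate_by_diel = c(DAWN = 0, DAY = 0,
                                                  DUSK = 0, NIGHT = 0),
                       seed = 30)
  s <- simulate_track(p, make_meta(tag_id = "Z", days = 10))
  expect_true(all(s$records$depth <= 50))
})

test_that("night-only excursions arrive at the Poisson rate", {
  p <- behavior_params(excursion_rate_by_diel = c(DAWN = 0, DAY = 0,
                                                  DUSK = 0, NIGHT = 0.2),
                       seed = 31)
  meta <- make_meta(tag_id = "P", days = 30)
  s <- simulate_track(p, meta)
  ev <- segment_excursions(s)
  a <- annotate_context(s)
  night_hours <- sum(a$diel == "NIGHT") * 2 / 60
  lambda <- 0.2 * night_hours
  expect_lt(abs(nrow(ev) - lambda), 3 * sqrt(lambda))
  # and the events are night-biased
  ev_diel <- a$diel[match(ev$start_time, a$timestamp) + 1]
  expect_gt(mean(ev_diel == "NIGHT", na.rm = TRUE), 0.8)
})

test_that("deep-record fraction rises monotonically with the diel rates", {
  meta <- make_meta(tag_id = "M", days = 15)
  fr <- sapply(c(1, 3, 9), function(mult) {
    p <- behavior_params(
      excursion_rate_by_diel = c(DAWN = 0.02, DAY = 0.02, DUSK = 0.02,
                                 NIGHT = 0.04) * mult,
      seed = 33)
    s <- simulate_track(p, meta)
    mean(s$records$depth > 50)
  })
  expect_true(all(diff(fr) > 0))
})

test_that("temperature is strictly anti-correlated with depth when noiseless", {
  p <- behavior_params(noise_sd_temp = 0, seed = 34)
  s <- simulate_track(p, make_meta(tag_id = "T", days = 5))
  # within a season, temperature is an affine decreasing function of depth
  a <- annotate_context(s)
  for (ss in unique(a$season)) {
    sub <- dplyr::filter(a, season == ss)
    expect_lt(cor(sub$depth, sub$temperature), -0.9999)
  }
})

test_that("mortality overlay produces sink, plateau and lagged temperature", {
  base <- simulate_track(behavior_params(seed = 40),
                         make_meta(tag_id = "MORT", days = 4))
  onset <- min(base$records$timestamp) + 6 * 3600
  expect_error(mortality_params(onset, temp_lag = 0), "at least 1")
  expect_error(
    simulate_mortality(base, mortality_params(
      onset = max(base$records$timestamp) + 86400)), "outside")

  m <- simulate_mortality(base, mortality_params(onset, temp_lag = 5))
  deep <- m$records$depth[m$records$timestamp > onset + 3 * 3600 &
                            m$records$timestamp < onset + 18 * 3600]
  expect_true(all(abs(deep - 1035) < 5))

  # cross-correlation argmax between depth and (negated) temperature diffs
  d <- diff(m$records$depth)
  tp <- -diff(m$records$temperature)
  cors <- sapply(0:10, function(L) {
    n <- length(d)
    cor(d[seq_len(n - L)], tp[seq_len(n - L) + L])
  })
  expect_equal(which.max(cors) - 1, 5)
})

test_that("transmission emulation subsamples and drops blocks deterministically", {
  s <- simulate_track(behavior_params(seed = 50),
                      make_meta(tag_id = "TX", days = 10))
  same <- emulate_transmission(s, 2, 0)
  expect_equal(same$records$depth, s$records$depth)

  hourly <- emulate_transmission(s, 60, 0)
  expect_equal(nrow(hourly$records), ceiling(nrow(s$records) / 30))
  expect_equal(hourly$metadata$nominal_resolution, 60)
  expect_false(hourly$metadata$recovered)

  dropped <- emulate_transmission(s, 60, 0.46, seed = 2)
  retained <- nrow(dropped$records) / nrow(hourly$records)
  expect_lt(abs(retained - 0.54), 0.05)
  again <- emulate_transmission(s, 60, 0.46, seed = 2)
  expect_identical(dropped$records, again$records)

  expect_error(emulate_transmission(s, 60, 1), "\\[0, 1\\)")
  expect_error(emulate_transmission(hourly, 2), "native")
})

test_that("directly simulated dive metrics sit near their type presets", {
  ev <- simulate_dive_metrics(3000, seed = 60)
  med <- ev |>
    dplyr::group_by(true_type) |>
    dplyr::summarise(depth = median(max_depth),
                     dur = median(duration_min),
                     sw = median(switch_count))
  expect_equal(med$depth[med$true_type == "TRANSITORY"], 60.2,
               tolerance = 0.05)
  expect_equal(med$depth[med$true_type == "DIRECTED"], 131.5,
               tolerance = 0.05)
  # durations are emergent from dive geometry: slow oscillatory extended
  # dives last longest, short shallow transitory forays shortest
  expect_gt(med$dur[med$true_type == "EXTENDED"],
            med$dur[med$true_type == "DIRECTED"])
  expect_gt(med$dur[med$true_type == "DIRECTED"],
            med$dur[med$true_type == "TRANSITORY"])
  expect_equal(med$sw[med$true_type == "EXTENDED"], 3)

  # an extended-heavy dive set couples oscillation count to duration
  heavy <- simulate_dive_metrics(
    800, type_mix = c(TRANSITORY = 0.2, EXTENDED = 0.6, DIRECTED = 0.2),
    seed = 61)
  sc <- switch_duration_correlation(heavy)
  expect_gt(sc$rho, 0.2)
  expect_lt(sc$p_value, 0.05)
})
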