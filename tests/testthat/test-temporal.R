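test_that("sunrise and sunset agree with an independent ephemeris oracle", {
  # Oracle values: solar altitude root-finding (-0.833 deg) with the
  # Astronomical Almanac low-precision solar position, computed separately
  # and frozen here (UTC).
  oracle <- tibble::tribble(
    ~date, ~lat, ~lon, ~sunrise, ~sunset,
    "2011-09-01", 24.8, -76.4, "10:46:30", "23:24:30",
    "2012-01-15", 24.8, -76.4, "11:52:30", "22:37:30",
    "2012-06-21", 24.601, -76.019, "10:16:30", "23:55:30",
    "2013-03-20", 24.601, -76.019, "11:07:30", "23:15:30"
  )
  for (i in seq_len(nrow(oracle))) {
    se <- solar_events(as.Date(oracle$date[i]), oracle$lat[i], oracle$lon[i])
    exp_sr <- as.POSIXct(paste(oracle$date[i], oracle$sunrise[i]), tz = "UTC")
    exp_ss <- as.POSIXct(paste(oracle$date[i], oracle$sunset[i]), tz = "UTC")
    expect_lt(abs(as.numeric(se$sunrise - exp_sr, units = "secs")), 180)
    expect_lt(abs(as.numeric(se$sunset - exp_ss, units = "secs")), 180)
    expect_lt(as.numeric(se$sunset - se$sunrise, units = "hours"), 24)
    expect_gt(as.numeric(se$sunset - se$sunrise, units = "hours"), 0)
  }
  # equator at equinox: sunrise ~06:00 local solar time
  se <- solar_events(as.Date("2012-03-20"), 0, 0)
  expect_lt(abs(as.numeric(se$sunrise -
    as.POSIXct("2012-03-20 06:00:00", tz = "UTC"), units = "mins")), 10)
  expect_error(solar_events(as.Date("2012-06-21"), 70, 0), "Polar")
})

test_that("diel assignment partitions the day with 2 h dawn/dusk windows", {
  se <- solar_events(as.Date("2012-06-21"), 24.8, -76.4)
  expect_equal(as.character(assign_diel(se$sunrise, se$sunrise, se$sunset)),
               "DAWN")
  expect_equal(as.character(assign_diel(se$sunrise + 3600, se$sunrise,
                                        se$sunset)), "DAY")
  expect_equal(as.character(assign_diel(se$sunset, se$sunrise, se$sunset)),
               "DUSK")
  expect_equal(as.character(assign_diel(se$sunset + 3600, se$sunrise,
                                        se$sunset)), "NIGHT")

  # counting oracle: over whole days at 1-min resolution, DAWN and DUSK
  # are exactly 120 min each and the four labels cover every minute
  for (d in as.Date(c("2012-02-01", "2012-08-15", "2012-11-05"))) {
    d <- as.Date(d, origin = "1970-01-01")
    se <- solar_events(d, 24.8, -76.4)
    mins <- as.POSIXct(d, tz = "UTC") + 5 * 3600 + seq(0, 1439) * 60
    diel <- assign_diel(mins, se$sunrise, se$sunset)
    expect_false(anyNA(diel))
    counts <- table(diel)
    expect_equal(unname(counts["DAWN"]), 120, ignore_attr = TRUE)
    expect_equal(unname(counts["DUSK"]), 120, ignore_attr = TRUE)
    expect_equal(sum(counts), 1440)
  }
})

test_that("lunar fraction matches USNO full/new moon dates and cycles", {
  # USNO-published phases: full 2011-09-12 and 2013-06-23; new 2011-08-29
  # and 2013-03-11
  expect_gte(lunar_fraction(as.Date("2011-09-12")), 0.97)
  expect_gte(lunar_fraction(as.Date("2013-06-23")), 0.97)
  expect_lte(lunar_fraction(as.Date("2011-08-29")), 0.03)
  expect_lte(lunar_fraction(as.Date("2013-03-11")), 0.03)

  # synodic cycle: successive full-moon peaks ~29.5 days apart
  dates <- as.Date("2012-01-01") + 0:365
  fr <- lunar_fraction(dates)
  peaks <- which(diff(sign(diff(fr))) == -2) + 1
  expect_true(all(diff(peaks) %in% 29:30))
})

test_that("moon bins are five monotone 20% levels", {
  b <- moon_bin(c(0, 0.19, 0.2, 0.55, 0.8, 0.99, 1))
  expect_equal(as.integer(b), c(1, 1, 2, 3, 5, 5, 5))
  expect_equal(nlevels(b), 5)
  expect_true(!is.unsorted(as.integer(moon_bin(seq(0, 1, 0.01)))))
})

test_that("meteorological seasons partition the calendar", {
  expect_equal(as.character(assign_season(as.Date("2012-01-01"))), "WINTER")
  expect_equal(as.character(assign_season(as.Date("2012-11-30"))), "AUTUMN")
  expect_equal(as.character(assign_season(as.Date("2012-12-01"))), "WINTER")
  all_days <- assign_season(as.Date("2012-01-01") + 0:365)
  expect_false(anyNA(all_days))
})

test_that("moon-phase eligibility requires two synodic months", {
  expect_true(moon_eligible(make_series(rep(10, 5), res = 60) |>
    (\(s) { s$metadata$popoff_date <- s$metadata$deploy_date + 59; s })()))
  short <- make_series(rep(10, 5))
  short$metadata$popoff_date <- short$metadata$deploy_date + 58
  expect_false(moon_eligible(short))
})

test_that("annotation attaches consistent context columns", {
  s <- simulate_track(behavior_params(seed = 2),
                      make_meta(tag_id = "ANN", days = 3))
  a <- annotate_context(s)
  expect_equal(nrow(a), nrow(s$records))
  expect_true(all(c("local_date", "diel", "moon_bin", "season") %in%
                    names(a)))
  expect_false(anyNA(a$diel))
  # dawn records sit within an hour of that day's sunrise
  dawn <- dplyr::filter(a, diel == "DAWN")
  expect_true(all(abs(as.numeric(dawn$timestamp - dawn$sunrise,
                                 units = "secs")) <= 3600))
})
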