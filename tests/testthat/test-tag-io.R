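test_that("a well-formed record file reads into a validated series", {
  tmp <- withr::local_tempdir()
  rec_path <- file.path(tmp, "rec.csv")
  meta_path <- file.path(tmp, "meta.csv")
  writeLines(c(
    "timestamp,depth,temperature,delta_limited",
    "2012-01-10T12:00:00Z,10.5,29.1,FALSE",
    "2012-01-10T12:02:00Z,-0.4,29.3,FALSE",
    "2012-01-10T12:04:00Z,12.0,29.0,TRUE"
  ), rec_path)
  readr::write_csv(make_meta(), meta_path)
  s <- read_tag_series(rec_path, meta_path)
  expect_s3_class(s, "tag_series")
  expect_equal(nrow(s$records), 3)
  # small negative depth accepted: clipped for analysis, preserved raw
  expect_equal(s$records$depth[2], 0)
  expect_equal(s$records$depth_raw[2], -0.4)
  expect_equal(sum(s$records$delta_limited), 1)
})

test_that("invalid inputs are refused with informative errors", {
  meta <- make_meta()
  t0 <- as.POSIXct("2012-01-10 12:00:00", tz = "UTC")
  expect_error(
    tag_series(tibble::tibble(timestamp = t0, depth = 5000), meta),
    class = "reefdive_validation_error"
  )
  expect_error(
    tag_series(tibble::tibble(timestamp = t0, wrong = 1), meta),
    class = "reefdive_format_error"
  )
  expect_error(
    tag_series(tibble::tibble(timestamp = t0, depth = 10,
                              temperature = 80), meta),
    class = "reefdive_validation_error"
  )
})

test_that("duplicate timestamps collapse to the first occurrence", {
  meta <- make_meta()
  t0 <- as.POSIXct("2012-01-10 12:00:00", tz = "UTC")
  rec <- tibble::tibble(timestamp = c(t0, t0, t0 + 120),
                        depth = c(10, 11, 12))
  expect_warning(s <- tag_series(rec, meta), "duplicate")
  expect_equal(nrow(s$records), 2)
  expect_equal(s$records$depth[1], 10)
})

test_that("write then read round-trips records exactly", {
  s <- make_series(c(10.4, 60.2, 33.7, 0.1, -0.3),
                   temperature = c(29.11, 27.52, 28.4, 29.9, 30))
  tmp <- withr::local_tempdir()
  write_tag_series(s, file.path(tmp, "r.csv"), file.path(tmp, "m.csv"))
  s2 <- read_tag_series(file.path(tmp, "r.csv"), file.path(tmp, "m.csv"))
  expect_equal(s2$records$timestamp, s$records$timestamp)
  expect_equal(s2$records$depth_raw, s$records$depth_raw)
  expect_equal(s2$records$depth, s$records$depth)
  expect_equal(s2$records$temperature, s$records$temperature)
})

test_that("gap detection finds dropped records and nothing else", {
  # one 10-min hole in a 2-min series
  depth <- rep(10, 10)
  s <- make_series(depth, res = 2)
  s$records <- s$records[-c(4, 5, 6, 7), ] # 12:06..12:12 removed
  g <- detect_gaps(s)
  expect_equal(nrow(g), 1)
  expect_equal(g$duration_min, 10)
  expect_true(g$start >= min(s$records$timestamp) &&
                g$end <= max(s$records$timestamp))

  # perfectly regular series: no gaps
  expect_equal(nrow(detect_gaps(make_series(rep(10, 50), res = 5))), 0)

  # every interval at 1.4x nominal stays under the 1.5x limit
  meta <- make_meta(res = 5)
  ts <- as.POSIXct("2012-01-10 12:00:00", tz = "UTC") + (0:49) * 7 * 60
  s3 <- tag_series(tibble::tibble(timestamp = ts, depth = 10), meta)
  dt <- as.numeric(diff(s3$records$timestamp), units = "mins")
  expect_true(all(dt <= 1.5 * 5)) # brute-force interval scan
  expect_equal(nrow(detect_gaps(s3)), 0)

  # gaps never overlap and order by time
  rw <- random_walk_series(11, n = 400, p_drop = 0.05)
  g2 <- detect_gaps(rw$series)
  if (nrow(g2) > 1) expect_true(all(g2$start[-1] >= g2$end[-nrow(g2)]))
})

test_that("series summaries match brute-force counts and ranges", {
  s <- make_series(c(3.2), res = 2)
  sm <- summarize_series(s)
  expect_equal(sm$depth_min, sm$depth_max)
  expect_equal(sm$n_records, 1)

  rw <- random_walk_series(5, n = 500, p_drop = 0)
  sm2 <- summarize_series(rw$series)
  expect_equal(sm2$n_records, length(rw$depth))
  expect_equal(sm2$depth_max, max(rw$depth))

  # a gap-free 30-day 2-min simulated track has exactly 30*720 records
  sim <- simulate_track(behavior_params(seed = 3),
                        make_meta(tag_id = "CNT", days = 30))
  expect_equal(summarize_series(sim)$n_records, 30 * 720)

  expect_error(summarize_series(make_series(numeric(0))), "empty")
})
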