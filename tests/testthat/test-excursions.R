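test_that("a minimal V excursion is segmented with boundary-to-boundary duration", {
  s <- make_series(c(10, 60, 10), res = 2)
  ev <- segment_excursions(s)
  expect_equal(nrow(ev), 1)
  expect_false(ev$rejected)
  expect_equal(ev$n_sub_records, 1L)
  expect_equal(ev$duration_min, 4) # two 2-min boundary intervals
  expect_equal(ev$switch_count, 1)
  expect_equal(ev$max_depth, 60)

  expect_equal(nrow(segment_excursions(make_series(c(10, 20, 30)))), 0)
})

test_that("dive metrics match hand-computed values", {
  s <- make_series(c(10, 60, 55, 70, 10), res = 2)
  ev <- segment_excursions(s)
  expect_equal(ev$switch_count, 3) # +,-,+,- signs: three changes

  s2 <- make_series(c(10, 70, 10), res = 2)
  ev2 <- segment_excursions(s2)
  expect_equal(ev2$mean_descent_rate, 60 / 120)
  expect_equal(ev2$mean_ascent_rate, 60 / 120)

  # zero differences (sensor quantisation plateaus) don't add switches
  m <- compute_dive_metrics(
    c(10, 60, 60, 60, 10),
    as.POSIXct("2012-01-01", tz = "UTC") + (0:4) * 120)
  expect_equal(m$switch_count, 1)
  expect_error(compute_dive_metrics(c(10, 60),
    as.POSIXct("2012-01-01", tz = "UTC") + (0:1) * 120), "3 records")
})

test_that("coarse series are refused and deep edges/gaps are rejected", {
  coarse <- make_series(c(10, 60, 10), res = 15, recovered = FALSE)
  expect_error(segment_excursions(coarse),
               class = "reefdive_eligibility_error")

  # series starting deep: first event has no start boundary
  s <- make_series(c(80, 60, 10, 60, 10))
  ev <- segment_excursions(s)
  expect_true(ev$rejected[1])
  expect_equal(ev$reject_reason[1], "truncated_at_series_edge")
  expect_false(ev$rejected[2])

  # an excursion spanning a temporal gap is rejected
  depth <- c(10, 60, 70, 65, 10, 10, 60, 10)
  s2 <- make_series(depth)
  s2$records <- s2$records[-3, ] # hole inside the first excursion
  ev2 <- segment_excursions(s2)
  expect_true(ev2$rejected[1])
  expect_equal(ev2$reject_reason[1], "temporal_gap")
  expect_false(ev2$rejected[2])
})

test_that("segmentation equals the brute-force oracle on random series", {
  for (seed in 1:25) {
    rw <- random_walk_series(seed)
    ev <- segment_excursions(rw$series)
    runs <- oracle_runs(rw$depth)
    expect_equal(nrow(ev), length(runs))
    if (length(runs) > 0) {
      expect_equal(ev$n_sub_records,
                   vapply(runs, function(r) r[2] - r[1] + 1L, 1L))
      # partition: every deep record in exactly one event
      expect_equal(sum(ev$n_sub_records), sum(rw$depth > 50))
    }
  }
})

test_that("single-sub-record dives have switch 1 and duration 2x interval", {
  for (seed in 26:35) {
    rw <- random_walk_series(seed, p_drop = 0)
    ev <- dplyr::filter(segment_excursions(rw$series),
                        n_sub_records == 1, !rejected)
    if (nrow(ev) > 0) {
      expect_true(all(ev$switch_count == 1))
      expect_true(all(ev$duration_min == 4))
    }
  }
})

test_that("inter-excursion statistics are order statistics of the gaps", {
  # five events starting exactly 1 h after the previous end
  depth <- rep(10, 32 * 5)
  idx <- (0:4) * 32 + 2
  depth[idx] <- 60
  s <- make_series(depth, res = 2)
  ev <- segment_excursions(s)
  st <- inter_excursion_stats(ev)
  expect_equal(st$n_intervals, 4)
  expect_equal(st$median_h, 1)
  expect_equal(st$iqr_h, 0)

  # constructed intervals {0.5, 1.6, 5.8} h
  starts <- cumsum(c(2, 0.5 * 30 + 2, 1.6 * 30 + 2, 5.8 * 30 + 2))
  depth2 <- rep(10, 400)
  depth2[starts] <- 60
  ev2 <- segment_excursions(make_series(depth2, res = 2))
  st2 <- inter_excursion_stats(ev2)
  expect_equal(st2$median_h, 1.6)
  expect_equal(st2$max_days, 5.8 / 24)

  expect_true(is.na(inter_excursion_stats(ev2[1, ])$median_h))
})

test_that("dive rates are counts over tracked hours and reconcile", {
  ev <- tibble::tibble(
    rejected = FALSE,
    label = factor(rep(c("TRANSITORY", "EXTENDED", "DIRECTED"),
                       c(30, 10, 0)),
                   levels = c("TRANSITORY", "EXTENDED", "DIRECTED"))
  )
  r <- dive_rates(ev, 300)
  expect_equal(r$rate_per_h[r$label == "TRANSITORY"], 0.10)
  expect_equal(r$rate_per_h[r$label == "DIRECTED"], 0)
  expect_equal(sum(r$rate_per_h * 300), nrow(ev))
  expect_error(dive_rates(dplyr::mutate(ev, label = NA), 300), "label")
})

test_that("switch-duration correlation behaves under dependence and independence", {
  ev <- tibble::tibble(rejected = FALSE, switch_count = 1:20,
                       duration_min = (1:20) * 3)
  expect_equal(switch_duration_correlation(ev)$rho, 1)

  set.seed(1)
  null_ev <- tibble::tibble(rejected = FALSE,
                            switch_count = sample(1:10, 500, TRUE),
                            duration_min = runif(500, 4, 100))
  res <- switch_duration_correlation(null_ev)
  expect_lt(abs(res$rho), 0.1)
  expect_gt(res$p_value, 0.05)

  const <- tibble::tibble(rejected = FALSE, switch_count = rep(1, 20),
                          duration_min = runif(20))
  expect_warning(res2 <- switch_duration_correlation(const), "Constant")
  expect_true(is.na(res2$rho))
})
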