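# Off-bank excursion segmentation and per-dive metrics. The bank edge in the
# study system is a near-vertical escarpment starting at 20-30 m, so a 50 m
# record is an unambiguous departure from shallow habitat.

EXCURSION_THRESHOLD_M <- 50
MAX_SEGMENTATION_RESOLUTION_MIN <- 5

#' Segment off-bank excursions from a tag series
#'
#' An excursion (dive event) is a maximal run of one or more consecutive
#' records strictly deeper than the threshold. Its start boundary is the last
#' record at or above the threshold immediately before the run, and its end
#' boundary the first such record after it, so duration is measured boundary
#' to boundary. Events that lack a boundary (the series starts or ends deep)
#' or whose boundary-to-boundary profile overlaps a temporal gap are retained
#' but marked `rejected` and excluded from metrics, rates and clustering.
#'
#' Only record sets at a temporal resolution of 5 min or finer resolve dive
#' structure; coarser series are refused.
#'
#' @param series A [tag_series()].
#' @param threshold Depth threshold in metres (default 50); records must be
#'   strictly deeper to count as off-bank.
#' @param gap_factor Gap-detection multiplier passed to [detect_gaps()].
#' @return A tibble, one row per event: `tag_id`, `event_id`, `start_time`,
#'   `end_time`, `n_sub_records`, `max_depth`, `duration_min`,
#'   `switch_count`, `mean_descent_rate`, `mean_ascent_rate`, `rejected`,
#'   `reject_reason`.
#' @export
segment_excursions <- function(series,
                               threshold = EXCURSION_THRESHOLD_M,
                               gap_factor = 1.5) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  res <- series$metadata$nominal_resolution
  if (res > MAX_SEGMENTATION_RESOLUTION_MIN) {
    abort(sprintf(
      "Series resolution (%g min) exceeds the %g-min eligibility limit for excursion analysis.",
      res, MAX_SEGMENTATION_RESOLUTION_MIN),
      class = "reefdive_eligibility_error")
  }
  r <- series$records
  n <- nrow(r)
  empty <- tibble(
    tag_id = character(), event_id = integer(),
    start_time = as.POSIXct(character(), tz = "UTC"),
    end_time = as.POSIXct(character(), tz = "UTC"),
    n_sub_records = integer(), max_depth = numeric(),
    duration_min = numeric(), switch_count = numeric(),
    mean_descent_rate = numeric(), mean_ascent_rate = numeric(),
    rejected = logical(), reject_reason = character()
  )
  if (n == 0) return(empty)

  deep <- r$depth > threshold
  if (!any(deep)) return(empty)
  runs <- rle(deep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sub_start <- starts[runs$values]
  sub_end <- ends[runs$values]

  gaps <- detect_gaps(series, factor = gap_factor)
  gap_after <- rep(FALSE, n) # gap between record i and i+1
  if (nrow(gaps) > 0) {
    gap_after[match(gaps$start, r$timestamp)] <- TRUE
  }

  events <- purrr::map2_dfr(sub_start, sub_end, function(i, j) {
    s <- i - 1L
    e <- j + 1L
    rejected <- FALSE
    reason <- NA_character_
    if (s < 1L || e > n) {
      rejected <- TRUE
      reason <- "truncated_at_series_edge"
      s <- max(s, 1L)
      e <- min(e, n)
    } else if (any(gap_after[s:(e - 1L)])) {
      rejected <- TRUE
      reason <- "temporal_gap"
    }
    prof <- r[s:e, ]
    met <- if (rejected) {
      list(duration = NA_real_, switches = NA_real_,
           descent = NA_real_, ascent = NA_real_)
    } else {
      dive_profile_metrics(prof$depth, prof$timestamp)
    }
    tibble(
      start_time = r$timestamp[s], end_time = r$timestamp[e],
      n_sub_records = j - i + 1L,
      max_depth = max(r$depth[i:j]),
      duration_min = met$duration, switch_count = met$switches,
      mean_descent_rate = met$descent, mean_ascent_rate = met$ascent,
      rejected = rejected, reject_reason = reason
    )
  })
  events %>%
    mutate(tag_id = series$metadata$tag_id,
           event_id = dplyr::row_number(), .before = 1)
}

# Metrics over a boundary-to-boundary profile: duration (min), switch count
# (sign changes of consecutive depth differences, zero differences ignored —
# sensor quantisation plateaus must not inflate oscillation counts), and
# mean descent/ascent rates (m/s) over all increasing/decreasing pairs.
dive_profile_metrics <- function(depth, timestamp) {
  dd <- diff(depth)
  dt <- as.numeric(diff(timestamp), units = "secs")
  duration <- as.numeric(difftime(timestamp[length(timestamp)], timestamp[1],
                                  units = "mins"))
  sgn <- sign(dd)
  sgn_nz <- sgn[sgn != 0]
  switches <- if (length(sgn_nz) < 2) 0 else sum(diff(sgn_nz) != 0)
  desc <- dd > 0
  asc <- dd < 0
  list(
    duration = duration,
    switches = switches,
    descent = if (any(desc)) mean(dd[desc] / dt[desc]) else NA_real_,
    ascent = if (any(asc)) mean(-dd[asc] / dt[asc]) else NA_real_
  )
}

#' Dive metrics for a boundary-to-boundary profile
#'
#' Computes the five characteristic dive variables for one excursion profile
#' (boundary record, sub-threshold records, boundary record): maximum depth,
#' boundary-to-boundary duration, switch count (vertical direction changes,
#' zero depth differences ignored), and mean descent and ascent rates over
#' all increasing/decreasing record pairs.
#'
#' @param depth Numeric depth vector (m), boundary records included.
#' @param timestamp POSIXct vector aligned with `depth`.
#' @return A one-row tibble: `max_depth`, `duration_min`, `switch_count`,
#'   `mean_descent_rate`, `mean_ascent_rate`.
#' @export
compute_dive_metrics <- function(depth, timestamp) {
  if (length(depth) < 3) {
    abort("A dive profile needs at least 3 records (two boundaries plus one sub-threshold record).")
  }
  met <- dive_profile_metrics(depth, timestamp)
  tibble(
    max_depth = max(depth[-c(1, length(depth))]),
    duration_min = met$duration,
    switch_count = met$switches,
    mean_descent_rate = met$descent,
    mean_ascent_rate = met$ascent
  )
}

accepted_events <- function(events) filter(events, !.data$rejected)

#' Inter-excursion interval statistics
#'
#' Intervals run from one accepted event's end boundary to the next one's
#' start boundary. Returned in the units the field reports: median and IQR in
#' hours, maximum in days.
#'
#' @param events Event tibble from [segment_excursions()].
#' @return A one-row tibble: `n_intervals`, `median_h`, `iqr_h`, `max_days`;
#'   `NA`s when fewer than two accepted events exist.
#' @export
inter_excursion_stats <- function(events) {
  ev <- accepted_events(events) %>% arrange(.data$start_time)
  if (nrow(ev) < 2) {
    return(tibble(n_intervals = 0L, median_h = NA_real_, iqr_h = NA_real_,
                  max_days = NA_real_))
  }
  iv_h <- as.numeric(difftime(ev$start_time[-1], ev$end_time[-nrow(ev)],
                              units = "hours"))
  tibble(
    n_intervals = length(iv_h),
    median_h = median(iv_h),
    iqr_h = unname(quantile(iv_h, 0.75) - quantile(iv_h, 0.25)),
    max_days = max(iv_h) / 24
  )
}

#' Per-type dive rates
#'
#' Dives per hour for each behavioural label, against the effectively tracked
#' time (deployment span minus gap time by default).
#'
#' @param events Labelled event tibble (column `label`); accepted events
#'   only are counted.
#' @param total_hours Tracked hours.
#' @return A tibble: `label`, `n`, `rate_per_h`, including zero rows for
#'   labels present as factor levels but unobserved.
#' @export
dive_rates <- function(events, total_hours) {
  if (total_hours <= 0) abort("`total_hours` must be positive.")
  ev <- accepted_events(events)
  if (!"label" %in% names(ev) || anyNA(ev$label)) {
    abort("All accepted events must carry a `label` before computing rates.")
  }
  ev %>%
    group_by(label = .data$label, .drop = FALSE) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>%
    mutate(rate_per_h = .data$n / total_hours)
}

#' Tracked hours of a series, excluding gap time
#'
#' @param series A [tag_series()].
#' @param gap_factor Gap-detection multiplier (default 1.5).
#' @param include_gaps If `TRUE`, return the raw span instead.
#' @return Hours of effective tracking.
#' @export
tracked_hours <- function(series, gap_factor = 1.5, include_gaps = FALSE) {
  r <- series$records
  span_h <- as.numeric(difftime(max(r$timestamp), min(r$timestamp),
                                units = "hours"))
  if (include_gaps) return(span_h)
  gaps <- detect_gaps(series, factor = gap_factor)
  span_h - sum(gaps$duration_min) / 60
}

#' Spearman correlation between switch count and dive duration
#'
#' Longer dives tend to contain more vertical oscillations; this quantifies
#' that with a rank correlation (average ranks on ties).
#'
#' @param events Event tibble from [segment_excursions()] (accepted events
#'   used; at least 10 required).
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
switch_duration_correlation <- function(events) {
  ev <- accepted_events(events)
  if (nrow(ev) < 10) abort("At least 10 accepted events are required.")
  if (sd(ev$switch_count) == 0 || sd(ev$duration_min) == 0) {
    warn("Constant metric; rank correlation is undefined.")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = nrow(ev)))
  }
  ct <- suppressWarnings(
    cor.test(ev$switch_count, ev$duration_min, method = "spearman",
             exact = FALSE)
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(ev))
}

#' Per-tag excursion summary
#'
#' One row per tag in the layout of a published off-bank excursion table:
#' percent of records deeper than the threshold, total accepted dive count,
#' inter-excursion interval statistics, and per-type dive rates when labels
#' are present.
#'
#' @param series A [tag_series()].
#' @param events Event tibble for this tag.
#' @param threshold Depth threshold (m).
#' @return A one-row tibble.
#' @export
excursion_summary <- function(series, events,
                              threshold = EXCURSION_THRESHOLD_M) {
  r <- series$records
  ev <- accepted_events(events)
  ies <- inter_excursion_stats(events)
  out <- tibble(
    tag_id = series$metadata$tag_id,
    pct_records_deep = 100 * sum(r$depth > threshold) / nrow(r),
    total_dive_count = nrow(ev),
    median_between_h = ies$median_h,
    iqr_between_h = ies$iqr_h,
    max_between_days = ies$max_days
  )
  if ("label" %in% names(ev) && nrow(ev) > 0 && !anyNA(ev$label)) {
    rates <- dive_rates(events, tracked_hours(series))
    wide <- tidyr::pivot_wider(
      select(rates, "label", "rate_per_h"),
      names_from = "label", values_from = "rate_per_h",
      names_glue = "rate_{tolower(label)}"
    )
    out <- dplyr::bind_cols(out, wide)
  }
  out
}

#' Plot a depth-versus-time profile
#'
#' Depth profile coloured by concurrent temperature, depth axis reversed
#' (surface at the top), with the excursion threshold marked.
#'
#' @param series A [tag_series()].
#' @param threshold Horizontal reference depth (default 50 m).
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(series, threshold = EXCURSION_THRESHOLD_M) {
  ggplot2::ggplot(series$records,
                  ggplot2::aes(x = .data$timestamp, y = .data$depth,
                               colour = .data$temperature)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(option = "plasma", name = "Temp (°C)") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Depth (m)",
                  title = series$metadata$tag_id) +
    ggplot2::theme_minimal()
}
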