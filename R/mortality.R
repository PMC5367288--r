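# Post-release mortality / tag-consumption screening. Two signatures: a long
# deep depth plateau (a sunk tag, or a tag inside a predator resting at the
# seafloor) and a temperature response lagging the depth profile (a tag
# reading a gut, not the water). Default thresholds separate a mortality
# trace (~1000 m for many hours) from the longest normal extended dives
# (< 7 h, far shallower holds) by a wide margin.

# For each window end hi, the smallest start lo such that
# max(x[lo:hi]) - min(x[lo:hi]) <= tol. Sliding-window two-pointer with
# monotonic deques; O(n).
window_starts_within_tolerance <- function(x, tol) {
  n <- length(x)
  maxdq <- integer(n)
  mindq <- integer(n)
  mh <- 1L; mt <- 0L
  nh <- 1L; nt <- 0L
  lo <- 1L
  out <- integer(n)
  for (hi in seq_len(n)) {
    while (mt >= mh && x[maxdq[mt]] <= x[hi]) mt <- mt - 1L
    mt <- mt + 1L
    maxdq[mt] <- hi
    while (nt >= nh && x[mindq[nt]] >= x[hi]) nt <- nt - 1L
    nt <- nt + 1L
    mindq[nt] <- hi
    while (x[maxdq[mh]] - x[mindq[nh]] > tol) {
      lo <- lo + 1L
      if (maxdq[mh] < lo) mh <- mh + 1L
      if (mindq[nh] < lo) nh <- nh + 1L
    }
    out[hi] <- lo
  }
  out
}

#' Detect a deep depth plateau
#'
#' Longest run of consecutive records deeper than `min_depth` whose depth
#' range stays within `tolerance`; reported if it lasts at least
#' `min_hours`.
#'
#' @param series A [tag_series()].
#' @param min_depth Minimum plateau depth, m (default 200).
#' @param min_hours Minimum plateau duration, hours (default 6).
#' @param tolerance Maximum within-plateau depth range, m (default 5).
#' @return A one-row tibble (`depth`, `start`, `duration_h`) or `NULL`.
#' @export
detect_plateau <- function(series, min_depth = 200, min_hours = 6,
                           tolerance = 5) {
  r <- series$records
  deep <- r$depth > min_depth
  if (!any(deep)) return(NULL)
  runs <- rle(deep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- NULL
  best_dur <- 0
  for (k in which(runs$values)) {
    i0 <- starts[k]
    j0 <- ends[k]
    x <- r$depth[i0:j0]
    lo_of <- window_starts_within_tolerance(x, tolerance)
    hi_idx <- i0:j0
    lo_idx <- i0 + lo_of - 1L
    dur <- as.numeric(difftime(r$timestamp[hi_idx], r$timestamp[lo_idx],
                               units = "hours"))
    w <- which.max(dur)
    if (dur[w] > best_dur) {
      best_dur <- dur[w]
      best <- c(lo_idx[w], hi_idx[w])
    }
  }
  if (is.null(best) || best_dur < min_hours) return(NULL)
  tibble(
    depth = mean(r$depth[best[1]:best[2]]),
    start = r$timestamp[best[1]],
    duration_h = best_dur
  )
}

#' Detect a temperature lag behind the depth profile
#'
#' Cross-correlates depth changes with (negated) temperature changes at lags
#' 0..`max_lag` samples. A lag is reported when the best lag is at least 1
#' and its correlation exceeds the lag-0 correlation by `margin` — a
#' normally functioning tag responds to ambient temperature within one
#' sample, so any resolvable delay is evidence of tag consumption.
#'
#' @param series A [tag_series()]; temperature must be present with at least
#'   500 paired records.
#' @param max_lag Maximum lag searched, samples (default 30).
#' @param margin Required correlation advantage over lag 0 (default 0.1).
#' @return A one-row tibble (`lag_samples`, `correlation`,
#'   `lag0_correlation`) or `NULL`.
#' @export
detect_temperature_lag <- function(series, max_lag = 30, margin = 0.1) {
  r <- series$records
  ok <- !is.na(r$temperature)
  if (sum(ok) < 500) {
    warn("Fewer than 500 paired depth/temperature records; lag not assessed.")
    return(NULL)
  }
  d <- diff(r$depth[ok])
  tp <- -diff(r$temperature[ok])
  n <- length(d)
  cors <- purrr::map_dbl(0:max_lag, function(L) {
    if (n - L < 100) return(NA_real_)
    suppressWarnings(cor(d[seq_len(n - L)], tp[seq_len(n - L) + L]))
  })
  if (all(is.na(cors))) return(NULL)
  best <- which.max(cors) - 1L
  if (best >= 1 && !is.na(cors[1]) &&
      cors[best + 1] > cors[1] + margin) {
    return(tibble(lag_samples = best, correlation = cors[best + 1],
                  lag0_correlation = cors[1]))
  }
  NULL
}

#' Screen a tag for post-release mortality signatures
#'
#' Runs both detectors and flags the tag if either triggers. Flagged tags
#' are excluded from all downstream analyses by [run_pipeline()] unless
#' overridden.
#'
#' @param series A [tag_series()].
#' @param min_depth,min_hours,tolerance Plateau-detector settings.
#' @param max_lag,margin Lag-detector settings.
#' @return An object of class `mortality_report`: list with `tag_id`,
#'   `flagged`, `plateau`, `temp_lag`, `evidence` (character vector of
#'   triggered rules).
#' @export
assess_mortality <- function(series, min_depth = 200, min_hours = 6,
                             tolerance = 5, max_lag = 30, margin = 0.1) {
  plateau <- detect_plateau(series, min_depth = min_depth,
                            min_hours = min_hours, tolerance = tolerance)
  lag <- detect_temperature_lag(series, max_lag = max_lag, margin = margin)
  evidence <- c(
    if (!is.null(plateau)) "deep_plateau",
    if (!is.null(lag)) "temperature_lag"
  )
  structure(list(
    tag_id = series$metadata$tag_id,
    flagged = length(evidence) > 0,
    plateau = plateau,
    temp_lag = lag,
    evidence = evidence %||% character()
  ), class = "mortality_report")
}

#' @exportS3Method base::print
print.mortality_report <- function(x, ...) {
  cat(sprintf("<mortality_report> %s: %s\n", x$tag_id,
              if (x$flagged) paste("FLAGGED -", paste(x$evidence, collapse = ", "))
              else "no mortality signature"))
  if (!is.null(x$plateau)) {
    cat(sprintf("  plateau at %.0f m for %.1f h\n",
                x$plateau$depth, x$plateau$duration_h))
  }
  if (!is.null(x$temp_lag)) {
    cat(sprintf("  temperature lag %d sample(s) (r = %.2f vs %.2f at lag 0)\n",
                x$temp_lag$lag_samples, x$temp_lag$correlation,
                x$temp_lag$lag0_correlation))
  }
  invisible(x)
}

#' Serialise a mortality report to JSON
#'
#' @param x A `mortality_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mortality_report <- function(x, path) {
  obj <- list(
    tag_id = x$tag_id, flagged = x$flagged,
    evidence = as.list(x$evidence),
    plateau = if (is.null(x$plateau)) NULL else as.list(x$plateau),
    temp_lag = if (is.null(x$temp_lag)) NULL else as.list(x$temp_lag)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, POSIXt = "ISO8601")
  invisible(path)
}
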