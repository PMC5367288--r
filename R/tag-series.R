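# Depth records are metres, positive down. Small negative depths are surface
# noise from the pressure sensor zero-offset; they are preserved in depth_raw
# and clipped to 0 in the analysis column.
DEPTH_MIN <- -1.0
DEPTH_MAX <- 2100
TEMP_MIN <- -5
TEMP_MAX <- 45

SITES <- c("SW_ELEUTHERA", "BRIDGE")
SEXES <- c("M", "F")
PROGRAMMING <- c("HR", "SR")

#' Construct tag deployment metadata
#'
#' One row of deployment metadata for a pop-up satellite archival tag (PSAT):
#' who the tag was on, where and when it was deployed, and how it sampled.
#'
#' @param tag_id Character tag identifier.
#' @param site Capture site, one of `"SW_ELEUTHERA"` or `"BRIDGE"`.
#' @param tag_lat,tag_lon Tagging location in decimal degrees (east-positive
#'   longitude).
#' @param length_stl Stretched total length of the animal, cm.
#' @param sex `"M"` or `"F"`.
#' @param deploy_date,popoff_date Deployment and pop-off dates (`Date` or
#'   coercible).
#' @param programming Tag programming mode: `"HR"` (high rate, ~5 min
#'   sampling, no geolocation) or `"SR"` (standard rate, 2 min archived,
#'   15–60 min transmitted).
#' @param nominal_resolution Nominal sampling interval of the record set in
#'   minutes (2–60).
#' @param recovered Logical; was the tag physically recovered (full archive
#'   available)?
#'
#' @return A one-row tibble of class `tag_metadata`.
#' @export
#' @examples
#' tag_metadata("T01", "BRIDGE", 24.6, -76.0, 180, "F",
#'              "2011-09-01", "2011-10-01", "SR", 2, TRUE)
tag_metadata <- function(tag_id, site, tag_lat, tag_lon, length_stl, sex,
                         deploy_date, popoff_date, programming,
                         nominal_resolution, recovered = FALSE) {
  site <- match.arg(site, SITES)
  sex <- match.arg(sex, SEXES)
  programming <- match.arg(programming, PROGRAMMING)
  deploy_date <- as.Date(deploy_date)
  popoff_date <- as.Date(popoff_date)
  if (popoff_date < deploy_date) {
    abort("`popoff_date` must be on or after `deploy_date`.")
  }
  if (nominal_resolution < 2 || nominal_resolution > 60) {
    abort("`nominal_resolution` must be between 2 and 60 minutes.")
  }
  if (programming == "HR" && abs(nominal_resolution - 5) > 1) {
    warn("HR tags normally sample at ~5 min; check `nominal_resolution`.")
  }
  if (programming == "SR" && isTRUE(recovered) && nominal_resolution != 2) {
    warn("Recovered SR archives are normally at 2-min resolution.")
  }
  tibble::new_tibble(
    tibble(
      tag_id = as.character(tag_id), site = site,
      tag_lat = as.numeric(tag_lat), tag_lon = as.numeric(tag_lon),
      length_stl = as.numeric(length_stl), sex = sex,
      deploy_date = deploy_date, popoff_date = popoff_date,
      programming = programming,
      nominal_resolution = as.numeric(nominal_resolution),
      recovered = isTRUE(recovered)
    ),
    class = "tag_metadata"
  )
}

#' Construct a validated tag time series
#'
#' Bundles a record table (timestamp, depth, temperature, delta-limited flag)
#' with its deployment metadata, after validation: records are sorted by time,
#' duplicate timestamps are collapsed to their first occurrence with a
#' warning, depths must lie in \[-1, 2100\] m and temperatures (when present)
#' in \[-5, 45\] °C, and records outside the deployment window are dropped
#' with a warning. Negative depths are kept in `depth_raw` and clipped to 0 in
#' `depth`.
#'
#' @param records A data frame with columns `timestamp` (POSIXct, UTC),
#'   `depth` (m), and optionally `temperature` (°C) and `delta_limited`
#'   (logical).
#' @param metadata A [tag_metadata()] row.
#'
#' @return An object of class `tag_series`: a list with elements `metadata`
#'   and `records` (a tibble).
#' @export
tag_series <- function(records, metadata) {
  stopifnot(inherits(metadata, "tag_metadata"))
  records <- tibble::as_tibble(records)
  required <- c("timestamp", "depth")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Record table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "reefdive_format_error")
  }
  if (!inherits(records$timestamp, "POSIXct")) {
    records$timestamp <- lubridate::ymd_hms(records$timestamp, tz = "UTC",
                                            quiet = TRUE)
    if (anyNA(records$timestamp)) {
      abort("Unparseable timestamps in record table.",
            class = "reefdive_format_error")
    }
  }
  if (!"temperature" %in% names(records)) records$temperature <- NA_real_
  if (!"delta_limited" %in% names(records)) records$delta_limited <- FALSE
  records$delta_limited[is.na(records$delta_limited)] <- FALSE

  bad_depth <- which(records$depth < DEPTH_MIN | records$depth > DEPTH_MAX)
  if (length(bad_depth) > 0) {
    abort(sprintf(
      "Depth out of bounds [%g, %g] m at record %d (depth = %g m).",
      DEPTH_MIN, DEPTH_MAX, bad_depth[1], records$depth[bad_depth[1]]),
      class = "reefdive_validation_error")
  }
  temp_ok <- is.na(records$temperature) |
    (records$temperature >= TEMP_MIN & records$temperature <= TEMP_MAX)
  if (!all(temp_ok)) {
    bad <- which(!temp_ok)[1]
    abort(sprintf(
      "Temperature out of bounds [%g, %g] degC at record %d (%g degC).",
      TEMP_MIN, TEMP_MAX, bad, records$temperature[bad]),
      class = "reefdive_validation_error")
  }

  records <- dplyr::arrange(records, .data$timestamp)
  dup <- duplicated(records$timestamp)
  if (any(dup)) {
    warn(sprintf("Collapsed %d duplicate timestamp(s); kept first occurrence.",
                 sum(dup)))
    records <- records[!dup, ]
  }

  window_lo <- as.POSIXct(metadata$deploy_date, tz = "UTC")
  window_hi <- as.POSIXct(metadata$popoff_date + 1, tz = "UTC")
  inside <- records$timestamp >= window_lo & records$timestamp < window_hi
  if (!all(inside)) {
    warn(sprintf("Dropped %d record(s) outside the deployment window.",
                 sum(!inside)))
    records <- records[inside, ]
  }

  records$depth_raw <- records$depth
  records$depth <- pmax(records$depth, 0)
  records <- dplyr::select(records, "timestamp", "depth", "temperature",
                           "delta_limited", "depth_raw")

  structure(list(metadata = metadata, records = records),
            class = "tag_series")
}

#' @exportS3Method base::print
print.tag_series <- function(x, ...) {
  m <- x$metadata
  cat(sprintf(
    "<tag_series> %s (%s, %s) %s tag, %.0f-min resolution\n",
    m$tag_id, m$site, m$sex, m$programming, m$nominal_resolution))
  cat(sprintf("  %d records, %s to %s\n", nrow(x$records),
              format(m$deploy_date), format(m$popoff_date)))
  invisible(x)
}

#' Extract the record table of a tag series
#'
#' @param x A [tag_series()].
#' @param ... Unused.
#' @return A tibble of records with a `tag_id` column prepended.
#' @export
tidy.tag_series <- function(x, ...) {
  dplyr::mutate(x$records, tag_id = x$metadata$tag_id, .before = 1)
}

n_records <- function(series) nrow(series$records)

#' Read a tag time series from delimited text
#'
#' Reads one tag's record CSV (columns `timestamp`, `depth`, optionally
#' `temperature`, `delta_limited`; ISO-8601 timestamps, UTC) together with a
#' metadata sidecar (CSV or YAML keyed by `tag_id`) and returns a validated
#' [tag_series()].
#'
#' @param path Path to the record CSV.
#' @param metadata_path Path to the metadata CSV or YAML file.
#' @param tag_id Tag to select from the metadata table; defaults to the only
#'   tag present.
#'
#' @return A [tag_series()].
#' @export
read_tag_series <- function(path, metadata_path, tag_id = NULL) {
  if (!file.exists(path)) abort(paste0("No such record file: ", path))
  if (!file.exists(metadata_path)) {
    abort(paste0("No such metadata file: ", metadata_path))
  }
  meta_tbl <- read_tag_metadata(metadata_path)
  if (is.null(tag_id)) {
    if (nrow(meta_tbl) != 1) {
      abort("Metadata file lists several tags; supply `tag_id`.")
    }
    tag_id <- meta_tbl$tag_id[1]
  }
  meta_row <- meta_tbl[meta_tbl$tag_id == tag_id, ]
  if (nrow(meta_row) == 0) {
    abort(paste0("Tag ", tag_id, " not found in metadata file."))
  }
  metadata <- do.call(tag_metadata, as.list(meta_row[1, ]))
  records <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tag_series(records, metadata)
}

#' Read a tag metadata table (CSV or YAML)
#'
#' @param path Path to a CSV with one row per tag, or a YAML mapping of
#'   `tag_id` to metadata fields.
#' @return A tibble, one row per tag.
#' @export
read_tag_metadata <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    tbl <- purrr::map_dfr(names(y), function(id) {
      tibble::as_tibble(c(list(tag_id = id), y[[id]]))
    })
  } else {
    # sex "F" must not parse as logical FALSE
    tbl <- readr::read_csv(
      path, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(
        tag_id = readr::col_character(), site = readr::col_character(),
        sex = readr::col_character(),
        programming = readr::col_character(),
        .default = readr::col_guess()
      )
    )
  }
  tbl$tag_id <- as.character(tbl$tag_id)
  tbl$deploy_date <- as.Date(tbl$deploy_date)
  tbl$popoff_date <- as.Date(tbl$popoff_date)
  tibble::as_tibble(tbl)
}

#' Write a tag series to delimited text
#'
#' Emits the same CSV dialect [read_tag_series()] reads, so a round trip
#' reproduces timestamps, depths and temperatures exactly at the written
#' precision. Raw (unclipped) depths are written.
#'
#' @param series A [tag_series()].
#' @param path Output record CSV path.
#' @param metadata_path Optional output metadata CSV path.
#' @return `path`, invisibly.
#' @export
write_tag_series <- function(series, path, metadata_path = NULL) {
  out <- tibble(
    timestamp = format(series$records$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC"),
    depth = series$records$depth_raw,
    temperature = series$records$temperature,
    delta_limited = series$records$delta_limited
  )
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(metadata_path)) {
    readr::write_csv(series$metadata, metadata_path, progress = FALSE)
  }
  invisible(path)
}

#' Detect temporal gaps in a tag series
#'
#' A gap is any interval between consecutive records longer than
#' `factor` times the tag's nominal sampling resolution. Tags transmit
#' through Argos with jitter, so a factor of 1.5 tolerates timing noise while
#' catching any fully dropped record.
#'
#' @param series A [tag_series()].
#' @param factor Positive multiplier of the nominal resolution (default 1.5).
#' @return A tibble with columns `start`, `end` (timestamps bounding each
#'   gap) and `duration_min`; zero rows when sampling is regular.
#' @export
detect_gaps <- function(series, factor = 1.5) {
  stopifnot(factor > 0)
  r <- series$records
  if (nrow(r) < 2) {
    inform("Fewer than 2 records; no gaps detectable.")
    return(tibble(start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  duration_min = numeric()))
  }
  dt <- as.numeric(difftime(r$timestamp[-1], r$timestamp[-nrow(r)],
                            units = "mins"))
  lim <- factor * series$metadata$nominal_resolution
  idx <- which(dt > lim)
  tibble(start = r$timestamp[idx], end = r$timestamp[idx + 1],
         duration_min = dt[idx])
}

#' Summarize a tag time series
#'
#' Counts and ranges over all records, delta-limited records included (their
#' truncated values are still valid observations of at-least-this-much
#' vertical change).
#'
#' @param series A [tag_series()].
#' @return A one-row tibble: `tag_id`, `n_records`, `depth_min`, `depth_max`,
#'   `temp_min`, `temp_max`, `n_delta_limited`, `duration_days`.
#' @export
summarize_series <- function(series) {
  r <- series$records
  if (nrow(r) == 0) abort("Cannot summarize an empty tag series.")
  tibble(
    tag_id = series$metadata$tag_id,
    n_records = nrow(r),
    depth_min = min(r$depth),
    depth_max = max(r$depth),
    temp_min = if (all(is.na(r$temperature))) NA_real_
               else min(r$temperature, na.rm = TRUE),
    temp_max = if (all(is.na(r$temperature))) NA_real_
               else max(r$temperature, na.rm = TRUE),
    n_delta_limited = sum(r$delta_limited),
    duration_days = as.numeric(difftime(max(r$timestamp), min(r$timestamp),
                                        units = "days"))
  )
}
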