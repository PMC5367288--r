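# Fixtures are built in code: small metadata/series constructors and
# independent brute-force oracles for segmentation and switch counting.

make_meta <- function(tag_id = "T1", res = 2, deploy = "2012-01-10",
                      days = 30, programming = "SR", site = "SW_ELEUTHERA",
                      sex = "F", lat = 24.8, lon = -76.4,
                      length_stl = 190, recovered = TRUE) {
  suppressWarnings(tag_metadata(
    tag_id = tag_id, site = site, tag_lat = lat, tag_lon = lon,
    length_stl = length_stl, sex = sex,
    deploy_date = as.Date(deploy), popoff_date = as.Date(deploy) + days,
    programming = programming, nominal_resolution = res,
    recovered = recovered
  ))
}

# A series from a depth vector on a regular grid (optionally with records
# deleted to create gaps via `keep`).
make_series <- function(depth, res = 2, start = "2012-01-10 12:00:00",
                        temperature = NULL, keep = NULL, tag_id = "T1",
                        ...) {
  n <- length(depth)
  t0 <- as.POSIXct(start, tz = "UTC")
  ts <- t0 + (seq_len(n) - 1) * res * 60
  days <- ceiling(n * res / 1440) + 2
  meta <- make_meta(tag_id = tag_id, res = res,
                    deploy = format(as.Date(t0) - 1), days = days + 2, ...)
  rec <- tibble::tibble(timestamp = ts, depth = depth)
  if (!is.null(temperature)) rec$temperature <- temperature
  if (!is.null(keep)) rec <- rec[keep, ]
  tag_series(rec, meta)
}

# Brute-force single-pass excursion oracle: maximal runs of depth > threshold
# as (first, last) record indices.
oracle_runs <- function(depth, threshold = 50) {
  out <- list()
  i <- 1L
  n <- length(depth)
  while (i <= n) {
    if (depth[i] > threshold) {
      j <- i
      while (j < n && depth[j + 1L] > threshold) j <- j + 1L
      out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Independent switch-count oracle: explicit loop over consecutive depth
# differences, skipping zeros.
oracle_switches <- function(depth) {
  dd <- diff(depth)
  dd <- dd[dd != 0]
  if (length(dd) < 2) return(if (length(dd) == 0) 0 else 0)
  s <- 0L
  for (k in 2:length(dd)) {
    if (sign(dd[k]) != sign(dd[k - 1])) s <- s + 1L
  }
  s
}

# Random depth series that crosses the 50 m threshold repeatedly, with
# optional random record deletions (temporal gaps).
random_walk_series <- function(seed, n = 300, res = 2, p_drop = 0.02) {
  set.seed(seed)
  depth <- pmin(pmax(45 + cumsum(rnorm(n, 0, 8)), 0), 400)
  keep <- which(runif(n) > p_drop)
  list(series = make_series(depth[keep], res = res,
                            tag_id = paste0("RW", seed)),
       depth = depth[keep])
}
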