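#' Kernel density estimate of a depth distribution
#'
#' Gaussian kernel density of the time-series depth records, with Silverman's
#' rule-of-thumb bandwidth (`bw.nrd0`) on a 512-point grid extended three
#' bandwidths beyond the data range — i.e. the defaults of R's `density()`,
#' which is also what practitioners apply to tag depth records.
#'
#' @param depths Numeric vector of depth records (m); at least 30 required.
#' @param grid_size Number of grid points (default 512).
#' @param bw Bandwidth specification passed to [stats::density()]
#'   (default `"nrd0"`).
#' @return A tibble with columns `depth` (grid, m) and `density`
#'   (probability density per metre); integrates to 1 by the trapezoid rule.
#' @export
estimate_depth_density <- function(depths, grid_size = 512, bw = "nrd0") {
  depths <- depths[!is.na(depths)]
  if (length(depths) < 30) {
    abort("At least 30 depth records are required for a density estimate.")
  }
  if (sd(depths) == 0) {
    abort("All depth records identical; density bandwidth is degenerate.")
  }
  d <- stats::density(depths, bw = bw, n = grid_size, cut = 3)
  tibble(depth = d$x, density = d$y)
}

#' Extract high-use depth bands from a depth density
#'
#' A high-use vertical depth band is a maximal contiguous run of density
#' grid points whose density exceeds `threshold` (per metre). Band edges are
#' reported at grid resolution and clipped below at 0 m (the surface);
#' per-band occupancy is the percentage of all records falling inside
#' \[lower, upper\].
#'
#' @param density_tbl Tibble from [estimate_depth_density()].
#' @param depths The depth records the density was computed from (m), used
#'   for occupancy percentages.
#' @param threshold Density threshold per metre (default 0.01).
#' @return A tibble of bands in increasing depth order: `lower`, `upper`,
#'   `width`, `pct_time`. Zero rows if no grid point exceeds the threshold.
#' @export
extract_bands <- function(density_tbl, depths, threshold = 0.01) {
  stopifnot(all(diff(density_tbl$depth) > 0))
  above <- density_tbl$density > threshold
  if (!any(above)) {
    inform("No density grid point exceeds the threshold; no bands.")
    return(tibble(lower = numeric(), upper = numeric(), width = numeric(),
                  pct_time = numeric()))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  bands <- tibble(
    lower = pmax(density_tbl$depth[starts[keep]], 0),
    upper = density_tbl$depth[ends[keep]]
  ) %>%
    filter(.data$upper > .data$lower) %>%
    mutate(width = .data$upper - .data$lower)
  depths <- depths[!is.na(depths)]
  bands$pct_time <- purrr::map2_dbl(bands$lower, bands$upper, function(lo, up) {
    100 * sum(depths >= lo & depths <= up) / length(depths)
  })
  arrange(bands, .data$lower)
}

#' Band occupancy percentages for a tag series
#'
#' Percent of records inside each (non-overlapping) depth band, and their
#' combined total.
#'
#' @param series A [tag_series()].
#' @param bands A tibble of bands (`lower`, `upper`), e.g. from
#'   [extract_bands()].
#' @return A list with `per_band` (the band tibble with `pct_time`
#'   recomputed) and `combined` (total percent across bands).
#' @export
band_occupancy <- function(series, bands) {
  if (nrow(bands) > 1) {
    b <- arrange(bands, .data$lower)
    if (any(b$lower[-1] < b$upper[-nrow(b)])) {
      abort("Depth bands overlap; occupancy percentages would double-count.")
    }
  }
  depths <- series$records$depth
  if (nrow(bands) == 0) {
    return(list(per_band = mutate(bands, pct_time = numeric(0)),
                combined = 0))
  }
  per <- purrr::map2_dbl(bands$lower, bands$upper, function(lo, up) {
    100 * sum(depths >= lo & depths <= up) / length(depths)
  })
  bands$pct_time <- per
  list(per_band = bands, combined = sum(per))
}

#' High-use depth bands for a tag series
#'
#' Convenience wrapper: density estimate, band extraction and occupancy in
#' one call, returning one summary row per tag in the layout of a published
#' band table (band ranges, widths, percent time).
#'
#' @param series A [tag_series()].
#' @param threshold Density threshold per metre (default 0.01).
#' @param grid_size Density grid size (default 512).
#' @return A list with `bands` (tibble of bands) and `summary` (one-row
#'   tibble: `tag_id`, `n_bands`, `band_ranges`, `band_widths`,
#'   `pct_time_total`).
#' @export
depth_bands <- function(series, threshold = 0.01, grid_size = 512) {
  dens <- estimate_depth_density(series$records$depth, grid_size = grid_size)
  bands <- extract_bands(dens, series$records$depth, threshold = threshold)
  occ <- band_occupancy(series, bands)
  summary <- tibble(
    tag_id = series$metadata$tag_id,
    n_bands = nrow(bands),
    band_ranges = paste(sprintf("%.1f-%.1f", bands$lower, bands$upper),
                        collapse = ", "),
    band_widths = paste(sprintf("%.1f", bands$width), collapse = ", "),
    pct_time_total = occ$combined
  )
  list(bands = occ$per_band, summary = summary, density = dens)
}

#' Plot a depth density with its high-use bands
#'
#' @param series A [tag_series()].
#' @param threshold Density threshold per metre (default 0.01).
#' @return A ggplot object: density vs depth with shaded bands and the
#'   threshold line.
#' @export
plot_depth_bands <- function(series, threshold = 0.01) {
  db <- depth_bands(series, threshold = threshold)
  ggplot2::ggplot(db$density, ggplot2::aes(x = .data$depth,
                                           y = .data$density)) +
    ggplot2::geom_rect(
      data = db$bands,
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Depth (m)", y = "Density (per m)",
                  title = series$metadata$tag_id) +
    ggplot2::theme_minimal()
}
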