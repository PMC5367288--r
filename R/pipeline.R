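#' Pipeline run configuration
#'
#' Thresholds, seeds and toggles for [run_pipeline()]. All thresholds must
#' be positive.
#'
#' @param out_dir Output directory (created if missing); `NULL` writes no
#'   files.
#' @param excursion_threshold Off-bank depth threshold, m (default 50).
#' @param density_threshold Depth-band density threshold per metre
#'   (default 0.01).
#' @param gap_factor Gap-detection multiplier (default 1.5).
#' @param alpha Significance level for elimination and contrasts
#'   (default 0.05).
#' @param k_override Optional fixed cluster count.
#' @param seed RNG seed for the clustering stage.
#' @param screen_mortality Run the mortality screen and exclude flagged
#'   tags (default `TRUE`).
#' @param enforce_moon_eligibility Drop the moon-phase effect when any
#'   modelled deployment is shorter than 59 days (default `TRUE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = NULL,
                       excursion_threshold = 50,
                       density_threshold = 0.01,
                       gap_factor = 1.5,
                       alpha = 0.05,
                       k_override = NULL,
                       seed = 1,
                       screen_mortality = TRUE,
                       enforce_moon_eligibility = TRUE) {
  stopifnot(excursion_threshold > 0, density_threshold > 0,
            gap_factor > 0, alpha > 0)
  structure(list(
    out_dir = out_dir,
    excursion_threshold = excursion_threshold,
    density_threshold = density_threshold,
    gap_factor = gap_factor,
    alpha = alpha,
    k_override = k_override,
    seed = seed,
    screen_mortality = screen_mortality,
    enforce_moon_eligibility = enforce_moon_eligibility
  ), class = "run_config")
}

#' Run the full vertical-habitat analysis pipeline
#'
#' Orchestrates: mortality screening (flagged tags excluded from every
#' further stage), context annotation, high-use depth bands, off-bank
#' excursion segmentation and metrics (tags at resolution <= 5 min only),
#' pooled dive classification, and the two mixed models with backward
#' elimination. Deterministic given the configuration and its seed. When
#' `config$out_dir` is set, CSV/JSON artefacts and a run log are written.
#'
#' @param tags A list of [tag_series()] objects.
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `band_table`,
#'   `excursion_table`, `cluster_model`, `cluster_table`, `events`,
#'   `model_depth`, `model_deep`, `model_table`, `excluded` (tibble of
#'   flagged tags), `log` (character).
#' @export
run_pipeline <- function(tags, config = run_config()) {
  stopifnot(length(tags) >= 1)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }
  ids <- purrr::map_chr(tags, ~ .x$metadata$tag_id)
  names(tags) <- ids
  say("pipeline: %d tag(s): %s", length(tags), paste(ids, collapse = ", "))

  # -- mortality screen ------------------------------------------------
  excluded <- tibble(tag_id = character(), evidence = character())
  if (config$screen_mortality) {
    reports <- purrr::map(tags, assess_mortality)
    flagged <- purrr::keep(reports, "flagged")
    if (length(flagged) > 0) {
      excluded <- purrr::map_dfr(flagged, function(rep) {
        tibble(tag_id = rep$tag_id,
               evidence = paste(rep$evidence, collapse = ";"))
      })
      say("mortality screen: excluded %s",
          paste(excluded$tag_id, collapse = ", "))
      tags <- tags[setdiff(names(tags), excluded$tag_id)]
    } else {
      say("mortality screen: no tags flagged")
    }
    if (length(tags) == 0) abort("All tags were flagged; nothing to analyse.")
  }

  # -- annotation ------------------------------------------------------
  annotated <- purrr::map(tags, annotate_context)
  say("annotation: %s records",
      format(sum(purrr::map_int(annotated, nrow)), big.mark = " "))

  # -- depth bands -----------------------------------------------------
  band_res <- purrr::map(tags, depth_bands,
                         threshold = config$density_threshold)
  band_table <- purrr::map_dfr(band_res, "summary")
  say("depth bands: %d tag(s), %s bands total", nrow(band_table),
      sum(band_table$n_bands))

  # -- excursions (<= 5 min resolution only) ---------------------------
  hi_res <- purrr::keep(tags, ~ .x$metadata$nominal_resolution <=
                          MAX_SEGMENTATION_RESOLUTION_MIN)
  say("excursions: %d of %d tag(s) at <= 5 min resolution",
      length(hi_res), length(tags))
  events <- purrr::map_dfr(hi_res, segment_excursions,
                           threshold = config$excursion_threshold,
                           gap_factor = config$gap_factor)
  excursion_table <- purrr::map_dfr(hi_res, function(s) {
    excursion_summary(s, filter(events, .data$tag_id == s$metadata$tag_id),
                      threshold = config$excursion_threshold)
  })
  say("excursions: %d events (%d accepted)", nrow(events),
      sum(!events$rejected))

  # -- dive classification (pooled across individuals) -----------------
  cluster_model <- NULL
  cluster_table <- NULL
  if (sum(!events$rejected) >= 10) {
    cluster_model <- classify_dives(events, seed = config$seed,
                                    k_override = config$k_override)
    cluster_table <- tidy(cluster_model)
    events <- events %>%
      left_join(select(cluster_model$events, "tag_id", "event_id", "label"),
                by = c("tag_id", "event_id"))
    # per-tag rates need labels
    excursion_table <- purrr::map_dfr(hi_res, function(s) {
      excursion_summary(s, filter(events, .data$tag_id == s$metadata$tag_id),
                        threshold = config$excursion_threshold)
    })
    say("clustering: k = %d, R2 = %.3f", cluster_model$chosen_k,
        cluster_model$r2)
  } else {
    say("clustering: skipped (fewer than 10 accepted events)")
  }

  # -- mixed models ----------------------------------------------------
  summaries <- purrr::imap_dfr(annotated, function(a, id) {
    aggregate_periods(a, tags[[id]]$metadata,
                      threshold = config$excursion_threshold)
  })
  dep_days <- purrr::map_dbl(tags, ~ as.numeric(
    .x$metadata$popoff_date - .x$metadata$deploy_date))
  model_depth <- NULL
  model_deep <- NULL
  model_table <- NULL
  if (length(tags) >= 2) {
    dd <- if (config$enforce_moon_eligibility) dep_days else NULL
    model_depth <- backward_eliminate(summaries, "MEAN_DEPTH",
                                      alpha = config$alpha,
                                      deployment_days = dd)
    model_deep <- backward_eliminate(summaries, "DEEP_COUNT",
                                     alpha = config$alpha,
                                     deployment_days = dd)
    model_table <- bind_rows(model_comparison(model_depth),
                             model_comparison(model_deep))
    say("models: depth retained {%s}; deep retained {%s}",
        paste(model_depth$retained, collapse = ", "),
        paste(model_deep$retained, collapse = ", "))
  } else {
    say("models: skipped (fewer than 2 individuals)")
  }

  result <- structure(list(
    band_table = band_table,
    excursion_table = excursion_table,
    events = events,
    cluster_model = cluster_model,
    cluster_table = cluster_table,
    summaries = summaries,
    model_depth = model_depth,
    model_deep = model_deep,
    model_table = model_table,
    excluded = excluded,
    log = log_lines
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    write_pipeline_result(result, config$out_dir)
  }
  result
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write pipeline artefacts to a directory
#'
#' Emits the band table, per-tag excursion table, per-event table, cluster
#' summary, model comparison table, exclusion list and run log as CSV/JSON/
#' text files.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory; created if missing.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    if (!is.null(x)) {
      readr::write_csv(x, file.path(out_dir, name), progress = FALSE)
    }
  }
  w(result$band_table, "depth_bands.csv")
  w(result$excursion_table, "excursion_summary.csv")
  w(result$events, "dive_events.csv")
  w(result$cluster_table, "cluster_summary.csv")
  w(result$model_table, "model_comparison.csv")
  w(result$excluded, "excluded_tags.csv")
  if (!is.null(result$cluster_model)) {
    write_cluster_model(result$cluster_model,
                        file.path(out_dir, "cluster_model.json"))
  }
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
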