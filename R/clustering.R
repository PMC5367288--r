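# PCA + k-means classification of dive events into behavioural types.
# Dives are classified on characteristic variables, not profile shape.

DIVE_FEATURES <- c("max_depth", "duration_min", "switch_count",
                   "mean_descent_rate", "mean_ascent_rate")
DIVE_TYPES <- c("TRANSITORY", "EXTENDED", "DIRECTED")
RATE_FLOOR <- 0.001 # m/s, keeps log finite below the printed 0.002 minimum

#' Build the log-scaled dive feature matrix
#'
#' Natural log of the five dive variables (vertical rates floored at
#' 0.001 m/s first), then per-column centring to mean 0 and scaling to SD 1.
#' Column order is fixed: max depth, duration, switch count, descent rate,
#' ascent rate.
#'
#' @param events Accepted dive events (tibble from [segment_excursions()]).
#' @param rate_floor Minimum rate substituted before the log (default 0.001).
#' @return A numeric matrix (n x 5) with attributes `feature_means` and
#'   `feature_sds` holding the log-scale scaling constants.
#' @export
build_feature_matrix <- function(events, rate_floor = RATE_FLOOR) {
  ev <- accepted_events(events)
  if (nrow(ev) < 10) abort("At least 10 accepted dive events are required.")
  x <- ev %>%
    mutate(
      mean_descent_rate = pmax(.data$mean_descent_rate, rate_floor),
      mean_ascent_rate = pmax(.data$mean_ascent_rate, rate_floor)
    ) %>%
    select(all_of(DIVE_FEATURES)) %>%
    as.matrix()
  if (any(x <= 0)) abort("All dive variables must be positive before log.")
  lx <- log(x)
  mu <- colMeans(lx)
  sds <- apply(lx, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero variance in variable(s): ",
                 paste(DIVE_FEATURES[sds == 0], collapse = ", ")))
  }
  out <- scale(lx, center = mu, scale = sds)
  attr(out, "feature_means") <- mu
  attr(out, "feature_sds") <- sds
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Principal components with latent-root retention
#'
#' Eigendecomposition of the correlation matrix of the (already scaled)
#' feature matrix. Components with eigenvalue >= 1 — the latent-root
#' (Kaiser) criterion — are retained for clustering. Loadings are
#' sign-normalised so each component's largest-magnitude loading is
#' positive.
#'
#' @param x Feature matrix from [build_feature_matrix()].
#' @return A list: `loadings` (5 x retained), `eigenvalues` (all 5),
#'   `var_explained` (proportions), `retained`, `scores` (n x retained).
#' @export
pca_retain <- function(x) {
  if (nrow(x) <= ncol(x)) abort("Need more events than features for PCA.")
  cm <- stats::cor(x)
  eg <- eigen(cm, symmetric = TRUE)
  evals <- eg$values
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  }
  retained <- max(1L, sum(evals >= 1))
  if (retained < sum(evals > 1e-10)) {
    # rank-deficiency or weak tail components simply aren't retained
  }
  loadings <- vecs[, seq_len(retained), drop = FALSE]
  rownames(loadings) <- colnames(x)
  list(
    loadings = loadings,
    eigenvalues = evals,
    var_explained = evals / length(evals),
    retained = retained,
    scores = x %*% loadings
  )
}

#' k-means over a range of k with an R-squared curve
#'
#' For each k, the best of `restarts` k-means fits (Hartigan-Wong) by total
#' within-cluster sum of squares; R-squared(k) = 1 - WSS(k)/TSS, the share of
#' dive-to-dive variation the clustering explains. Deterministic given
#' `seed`.
#'
#' @param scores Score matrix from [pca_retain()].
#' @param k_range Integer vector of cluster counts (default 1:8).
#' @param restarts Random restarts per k (default 20).
#' @param seed RNG seed.
#' @return A list: `r2_curve` (tibble `k`, `r2`) and `fits` (named list of
#'   `kmeans` objects).
#' @export
kmeans_r2 <- function(scores, k_range = 1:8, restarts = 20, seed = 1) {
  n <- nrow(scores)
  k_range <- k_range[k_range <= n]
  if (length(k_range) < length(1:8)) {
    if (any(1:8 > n)) warn("Some k exceed the number of events; skipped.")
  }
  tss <- sum(scale(scores, scale = FALSE)^2)
  fits <- list()
  r2 <- numeric(length(k_range))
  set.seed(seed)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- if (k == 1) {
      stats::kmeans(scores, centers = 1)
    } else if (k == n) {
      # every point its own cluster: WSS is exactly 0
      structure(list(cluster = seq_len(n), centers = scores,
                     totss = tss, withinss = rep(0, n), tot.withinss = 0,
                     betweenss = tss, size = rep(1L, n)),
                class = "kmeans")
    } else {
      stats::kmeans(scores, centers = k, nstart = restarts,
                    iter.max = 50)
    }
    fits[[as.character(k)]] <- fit
    r2[i] <- 1 - fit$tot.withinss / tss
  }
  list(r2_curve = tibble(k = k_range, r2 = r2), fits = fits)
}

#' Choose the number of clusters from the R-squared curve
#'
#' The published rule is visual ("R-squared versus cluster number"); the
#' implemented criterion is the smallest k whose marginal R-squared gain to
#' k+1 falls below `min_gain`. An override pins k (e.g. to 3) regardless.
#'
#' @param r2_curve Tibble (`k`, `r2`) from [kmeans_r2()].
#' @param min_gain Marginal-gain cutoff (default 0.1, calibrated so the
#'   bundled three-type preset yields k = 3; the published rule is visual).
#' @param k_override Optional fixed k.
#' @return Chosen k (integer).
#' @export
select_k <- function(r2_curve, min_gain = 0.1, k_override = NULL) {
  if (!is.null(k_override)) return(as.integer(k_override))
  if (nrow(r2_curve) < 3) abort("R-squared curve must cover at least 3 k values.")
  r2_curve <- arrange(r2_curve, .data$k)
  gains <- diff(r2_curve$r2)
  below <- which(gains < min_gain)
  if (length(below) == 0) return(as.integer(max(r2_curve$k)))
  as.integer(r2_curve$k[below[1]])
}

#' Attach semantic labels to clusters
#'
#' With three clusters the behavioural naming is: DIRECTED = highest median
#' maximum depth; EXTENDED = highest median duration among the rest;
#' TRANSITORY = the remainder. Directed dives should also show the fastest
#' median descent rate; a warning is emitted if they do not. Any other k
#' yields generic `CLUSTER_i` labels.
#'
#' @param assignment Integer cluster assignment (one per event).
#' @param events The accepted events the assignment refers to, in the same
#'   order.
#' @return A character vector mapping cluster index to label
#'   (`labels[assignment]` labels each event).
#' @export
label_clusters <- function(assignment, events) {
  ev <- accepted_events(events)
  stopifnot(nrow(ev) == length(assignment))
  k <- length(unique(assignment))
  if (k != 3) {
    return(setNames(paste0("CLUSTER_", sort(unique(assignment))),
                    sort(unique(assignment))))
  }
  med <- tibble(cluster = assignment,
                max_depth = ev$max_depth,
                duration = ev$duration_min,
                descent = ev$mean_descent_rate) %>%
    group_by(.data$cluster) %>%
    summarise(across(c("max_depth", "duration", "descent"), median),
              .groups = "drop")
  # ties in the depth median broken by descent rate
  med <- arrange(med, dplyr::desc(.data$max_depth), dplyr::desc(.data$descent))
  directed <- med$cluster[1]
  rest <- filter(med, .data$cluster != directed) %>%
    arrange(dplyr::desc(.data$duration), dplyr::desc(.data$max_depth))
  extended <- rest$cluster[1]
  transitory <- rest$cluster[2]
  if (med$descent[med$cluster == directed] < max(med$descent)) {
    warn("Directed cluster does not have the fastest median descent rate.")
  }
  out <- character(3)
  out[c(directed, extended, transitory)] <-
    c("DIRECTED", "EXTENDED", "TRANSITORY")
  setNames(out, seq_len(3))
}

#' Classify dive events into behavioural types
#'
#' The full classification stage: log/scale/centre the five dive variables,
#' retain principal components by the latent-root criterion, run k-means
#' across `k_range` with restarts, choose k from the R-squared elbow (or an
#' override), and attach semantic labels.
#'
#' @param events Dive events (accepted rows are used).
#' @param k_range Candidate cluster counts (default 1:8).
#' @param restarts k-means restarts (default 20).
#' @param seed RNG seed (default 1).
#' @param min_gain Elbow cutoff for [select_k()].
#' @param k_override Optional fixed k.
#' @return An object of class `dive_cluster_model`; see [tidy.dive_cluster_model()],
#'   [glance.dive_cluster_model()], [autoplot.dive_cluster_model()]. The
#'   element `events` is the accepted-event tibble with a `label` column.
#' @export
classify_dives <- function(events, k_range = 1:8, restarts = 20, seed = 1,
                           min_gain = 0.1, k_override = NULL) {
  ev <- accepted_events(events)
  x <- build_feature_matrix(events)
  pca <- pca_retain(x)
  km <- kmeans_r2(pca$scores, k_range = k_range, restarts = restarts,
                  seed = seed)
  chosen_k <- select_k(km$r2_curve, min_gain = min_gain,
                       k_override = k_override)
  fit <- km$fits[[as.character(chosen_k)]]
  labels <- label_clusters(fit$cluster, events)
  ev$cluster <- fit$cluster
  ev$label <- factor(labels[as.character(fit$cluster)],
                     levels = if (chosen_k == 3) DIVE_TYPES
                              else unname(labels))
  structure(list(
    feature_means = attr(x, "feature_means"),
    feature_sds = attr(x, "feature_sds"),
    loadings = pca$loadings,
    eigenvalues = pca$eigenvalues,
    var_explained = pca$var_explained,
    retained = pca$retained,
    scores = pca$scores,
    r2_curve = km$r2_curve,
    chosen_k = chosen_k,
    r2 = km$r2_curve$r2[km$r2_curve$k == chosen_k],
    centroids = fit$centers,
    cluster = fit$cluster,
    labels = labels,
    events = ev,
    seed = seed
  ), class = "dive_cluster_model")
}

#' @exportS3Method base::print
print.dive_cluster_model <- function(x, ...) {
  cat(sprintf(
    "<dive_cluster_model> %d dives, %d retained component(s), k = %d (R2 = %.3f)\n",
    nrow(x$events), x$retained, x$chosen_k, x$r2))
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster dive statistics
#'
#' Median (IQR) and range of the five dive variables by behavioural label —
#' the layout of a published dive-cluster summary table.
#'
#' @param x A `dive_cluster_model`.
#' @param ... Unused.
#' @return A tibble, one row per cluster x variable.
#' @export
tidy.dive_cluster_model <- function(x, ...) {
  x$events %>%
    tidyr::pivot_longer(all_of(DIVE_FEATURES), names_to = "variable",
                        values_to = "value") %>%
    group_by(.data$label, .data$variable) %>%
    summarise(
      n = dplyr::n(),
      median = median(.data$value),
      iqr = unname(quantile(.data$value, 0.75) - quantile(.data$value, 0.25)),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
}

#' One-row model summary
#'
#' @param x A `dive_cluster_model`.
#' @param ... Unused.
#' @return A one-row tibble: `n_dives`, `retained`, `pc1_var`, `pc2_var`,
#'   `chosen_k`, `r2`.
#' @export
glance.dive_cluster_model <- function(x, ...) {
  tibble(
    n_dives = nrow(x$events),
    retained = x$retained,
    pc1_var = x$var_explained[1],
    pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_,
    chosen_k = x$chosen_k,
    r2 = x$r2
  )
}

#' Score-space plot of a dive classification
#'
#' @param object A `dive_cluster_model`.
#' @param ... Unused.
#' @return A ggplot of the first two component scores coloured by label
#'   (or PC1 vs dive index when only one component was retained).
#' @export
autoplot.dive_cluster_model <- function(object, ...) {
  sc <- object$scores
  df <- tibble(
    pc1 = sc[, 1],
    pc2 = if (ncol(sc) > 1) sc[, 2] else seq_len(nrow(sc)),
    label = object$events$label
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = if (ncol(sc) > 1)
        sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
      else "Dive index",
      colour = "Dive type"
    ) +
    ggplot2::theme_minimal()
}

#' Serialise a cluster model to JSON
#'
#' Dumps scaling constants, loadings, eigenvalues, centroids, the R-squared
#' curve and labels so a classification can be archived or re-applied.
#'
#' @param x A `dive_cluster_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(x, path) {
  obj <- list(
    feature_means = as.list(x$feature_means),
    feature_sds = as.list(x$feature_sds),
    loadings = unclass(x$loadings),
    eigenvalues = x$eigenvalues,
    retained = x$retained,
    centroids = unclass(x$centroids),
    r2_curve = x$r2_curve,
    chosen_k = x$chosen_k,
    labels = as.list(x$labels),
    seed = x$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
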