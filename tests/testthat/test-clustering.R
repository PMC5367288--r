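test_that("the feature matrix is log-scaled with a fixed column order", {
  ev <- simulate_dive_metrics(200, seed = 3)
  x <- build_feature_matrix(ev)
  expect_equal(colnames(x), c("max_depth", "duration_min", "switch_count",
                              "mean_descent_rate", "mean_ascent_rate"))
  expect_true(all(abs(colMeans(x)) < 1e-10))
  expect_true(all(abs(apply(x, 2, sd) - 1) < 1e-10))

  const <- dplyr::mutate(ev, switch_count = 3)
  expect_error(build_feature_matrix(const), "switch_count")
  expect_error(build_feature_matrix(ev[1:5, ]), "10")
})

test_that("rates below the floor are lifted before the log", {
  ev <- simulate_dive_metrics(50, seed = 4)
  ev$mean_descent_rate[1] <- 1e-6
  expect_silent(x <- build_feature_matrix(ev))
  expect_true(all(is.finite(x)))
})

test_that("latent-root retention matches analytic correlation structure", {
  set.seed(10)
  # five independent standard normals: all eigenvalues near 1
  x <- scale(matrix(rnorm(5 * 4000), ncol = 5))
  colnames(x) <- paste0("v", 1:5)
  p <- pca_retain(x)
  expect_true(all(abs(p$eigenvalues - 1) < 0.15))
  expect_lt(abs(sum(p$eigenvalues) - 5), 1e-8)

  # two perfectly correlated blocks: eigenvalues 3 and 2, two retained
  z1 <- rnorm(1000); z2 <- rnorm(1000)
  xb <- cbind(z1, z1, z1, z2, z2) + matrix(rnorm(5000, 0, 1e-6), ncol = 5)
  xb <- scale(xb)
  colnames(xb) <- paste0("v", 1:5)
  pb <- pca_retain(xb)
  expect_equal(pb$retained, 2)
  expect_lt(abs(pb$eigenvalues[1] - 3), 0.05)
  expect_lt(abs(pb$eigenvalues[2] - 2), 0.05)
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(pb$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
})

test_that("the R-squared curve has its definitional endpoints and elbow", {
  set.seed(11)
  blobs <- rbind(matrix(rnorm(200, 0, 0.3), ncol = 2),
                 matrix(rnorm(200, 5, 0.3), ncol = 2),
                 matrix(rnorm(200, c(0, 8), 0.3), ncol = 2))
  km <- kmeans_r2(blobs, k_range = 1:6, seed = 5)
  expect_equal(km$r2_curve$r2[1], 0)
  expect_true(!is.unsorted(km$r2_curve$r2))
  gains <- diff(km$r2_curve$r2)
  expect_lt(gains[3], 0.1 * gains[2]) # elbow at k = 3

  tiny <- matrix(rnorm(24), ncol = 2)
  km2 <- suppressWarnings(kmeans_r2(tiny, k_range = c(1:3, 12), seed = 1))
  expect_equal(km2$r2_curve$r2[km2$r2_curve$k == 12], 1)
})

test_that("k selection applies the marginal-gain rule", {
  curve <- tibble::tibble(k = 1:4, r2 = c(0, 0.4, 0.6, 0.63))
  expect_equal(select_k(curve), 3L)
  flat <- tibble::tibble(k = 1:3, r2 = c(0, 0.02, 0.03))
  expect_equal(select_k(flat), 1L)
  expect_equal(select_k(flat, k_override = 3), 3L)
})

test_that("semantic labels recover generator types and ignore index permutation", {
  ev <- simulate_dive_metrics(300, seed = 6)
  x <- build_feature_matrix(ev)
  sc <- pca_retain(x)$scores
  set.seed(2)
  fit <- stats::kmeans(sc, 3, nstart = 20)
  labels <- label_clusters(fit$cluster, ev)
  agree <- mean(labels[as.character(fit$cluster)] == ev$true_type)
  expect_gte(agree, 0.85)

  # permuting cluster indices permutes the map but not per-event labels
  perm <- c(2, 3, 1)
  relabeled <- label_clusters(perm[fit$cluster], ev)
  expect_equal(unname(relabeled[as.character(perm[fit$cluster])]),
               unname(labels[as.character(fit$cluster)]))

  # non-three k gets generic labels
  fit2 <- stats::kmeans(sc, 2, nstart = 5)
  expect_equal(unname(label_clusters(fit2$cluster, ev)),
               c("CLUSTER_1", "CLUSTER_2"))
})

test_that("classification is deterministic given the seed", {
  ev <- simulate_dive_metrics(250, seed = 8)
  m1 <- classify_dives(ev, seed = 99)
  m2 <- classify_dives(ev, seed = 99)
  expect_equal(m1$r2_curve, m2$r2_curve)
  expect_equal(m1$cluster, m2$cluster)
  expect_equal(m1$labels, m2$labels)
  g <- glance(m1)
  expect_equal(g$chosen_k, m1$chosen_k)
  td <- tidy(m1)
  expect_equal(sort(unique(as.character(td$label))),
               sort(unique(as.character(m1$events$label))))
})
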