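test_that("the four-point toy clustering reproduces every hand-computed index", {
  toy <- toy_ab()
  cm <- build_cluster_model(toy$X, toy$lab)

  s <- silhouette_values(toy$X, cm, "euclidean")
  expect_equal(s$a, rep(1, 4))
  expect_equal(s$b, rep((10 + sqrt(101)) / 2, 4))
  expect_equal(s$mean_sc, 0.9002, tolerance = 1e-4)

  d <- dunn_index(toy$X, cm, "euclidean")
  expect_equal(d$d_cmin, 10)
  expect_equal(d$d_max, 1)
  expect_equal(d$value, 10)

  db <- davies_bouldin(toy$X, cm, "euclidean")
  expect_equal(db$value, 0.2)
  expect_equal(davies_bouldin(toy$X, cm, "euclidean", "mean")$value, 0.1)

  expect_equal(calinski_harabasz(toy$X, cm), 200)
})

test_that("silhouette conventions: perfect cohesion scores 1, singletons 0", {
  X <- rbind(c(1, 1), c(1, 1), c(5, 5), c(5, 6))
  cm <- build_cluster_model(X, c(1L, 1L, 2L, 2L))
  s <- silhouette_values(X, cm, "euclidean")
  expect_equal(s$sc[1:2], c(1, 1))

  X3 <- rbind(c(0, 0), c(1, 0), c(2, 0))
  cm3 <- build_cluster_model(X3, 1:3)
  s3 <- silhouette_values(X3, cm3, "euclidean")
  expect_equal(s3$sc, c(0, 0, 0))
  expect_error(silhouette_values(X3, build_cluster_model(X3, c(1L, 1L, 1L))),
               "non-empty")
})

test_that("silhouette values stay in [-1, 1] and match the brute-force oracle", {
  for (s in 1:60) {
    ds <- random_labeled_dataset(s)
    cm <- build_cluster_model(ds$X, ds$lab, n_clusters = ds$m)
    mine <- silhouette_values(ds$X, cm, "euclidean")
    expect_true(all(mine$sc >= -1 - 1e-12 & mine$sc <= 1 + 1e-12))
    expect_equal(mine$sc, oracle_silhouette(ds$X, ds$lab), tolerance = 1e-8)
  }
})

test_that("silhouette agrees with the cluster package on random datasets", {
  skip_if_not_installed("cluster")
  for (s in 101:130) {
    ds <- random_labeled_dataset(s)
    cm <- build_cluster_model(ds$X, ds$lab, n_clusters = ds$m)
    mine <- silhouette_values(ds$X, cm, "euclidean")
    ref <- cluster::silhouette(ds$lab, dist(ds$X))
    expect_equal(mine$sc, unname(ref[, "sil_width"]), tolerance = 1e-8)
  }
})

test_that("Dunn index degeneracies and monotonicity behave as defined", {
  toy <- toy_ab()
  cm <- build_cluster_model(toy$X, toy$lab)
  d0 <- dunn_index(toy$X, cm, "euclidean")$value
  far <- toy$X
  far[3:4, 1] <- far[3:4, 1] + 50 # translate cluster B rigidly away
  d1 <- dunn_index(far, build_cluster_model(far, toy$lab), "euclidean")$value
  expect_gt(d1, d0)

  dup <- rbind(c(0, 0), c(0, 2), c(0, 0), c(0, 2))
  dd <- dunn_index(dup, build_cluster_model(dup, c(1L, 1L, 2L, 2L)),
                   "euclidean")
  expect_equal(dd$value, 0) # coincident centroids

  sing <- rbind(c(0, 0), c(5, 5), c(9, 9))
  dsing <- dunn_index(sing, build_cluster_model(sing, 1:3), "euclidean")
  expect_true(dsing$degenerate)
  expect_equal(dsing$value, Inf)
})

test_that("Davies-Bouldin: the printed sum equals M times the classical mean", {
  for (s in 1:25) {
    ds <- random_labeled_dataset(s)
    cm <- build_cluster_model(ds$X, ds$lab, n_clusters = ds$m)
    total <- davies_bouldin(ds$X, cm, "euclidean")$value
    avg <- davies_bouldin(ds$X, cm, "euclidean", "mean")$value
    expect_equal(total, ds$m * avg, tolerance = 1e-12)
    expect_gte(avg, 0)
    expect_equal(avg, oracle_db_mean(ds$X, ds$lab), tolerance = 1e-8)
  }
})

test_that("Calinski-Harabasz matches the oracle and the scatter decomposition", {
  for (s in 1:40) {
    ds <- random_labeled_dataset(s)
    cm <- build_cluster_model(ds$X, ds$lab, n_clusters = ds$m)
    ch <- calinski_harabasz(ds$X, cm)
    expect_equal(ch, oracle_ch(ds$X, ds$lab), tolerance = 1e-6)
    # independent route: between = total scatter - within
    g <- colMeans(ds$X)
    total <- sum(sweep(ds$X, 2, g)^2)
    within <- sum(sapply(seq_len(nrow(ds$X)), function(j) {
      sum((ds$X[j, ] - cm$centroids[ds$lab[j], ])^2)
    }))
    n <- nrow(ds$X)
    expect_equal(ch, ((total - within) / (ds$m - 1)) / (within / (n - ds$m)),
                 tolerance = 1e-6)
  }
  toy <- toy_ab()
  expect_error(
    calinski_harabasz(toy$X[1:2, ],
                      build_cluster_model(toy$X[1:2, ], 1:2)),
    "N > M")
})

test_that("cosine-metric indices ignore positive per-point rescaling", {
  set.seed(77)
  X <- matrix(runif(60, 1, 4), 20, 3)
  lab <- rep(1:2, each = 10)
  scale <- runif(20, 0.2, 5)
  Xs <- X * scale
  cm <- build_cluster_model(X, lab)
  cms <- build_cluster_model(Xs, lab)
  s1 <- silhouette_values(X, cm, "cosine")$sc
  s2 <- silhouette_values(Xs, cms, "cosine")$sc
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("the aggregated report assembles all five scores with flags", {
  toy <- toy_ab()
  cm <- build_cluster_model(toy$X, toy$lab)
  som <- init_som(2, 2, som_config(seed = 1))
  som$weights <- cm$centroids
  som$metric <- "euclidean"
  rep1 <- compute_report(toy$X, cm, som)
  expect_equal(rep1$sc_mean, 0.9002, tolerance = 1e-4)
  expect_equal(rep1$dunn, 10)
  expect_equal(rep1$dbi, 0.2)
  expect_equal(rep1$ch, 200)
  expect_equal(rep1$qe, 0.25)
  expect_length(rep1$flags$empty_clusters, 0)

  rep2 <- compute_report(toy$X, cm, som)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))

  cm3 <- build_cluster_model(toy$X, toy$lab, n_clusters = 3)
  rep3 <- compute_report(toy$X, cm3, som)
  expect_equal(rep3$flags$empty_clusters, 3L)
})
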