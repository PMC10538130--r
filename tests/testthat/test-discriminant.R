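test_that("ds_vector matches the normalized-inverse form and its zero branch", {
  cm <- build_cluster_model(rbind(c(0, 0), c(4, 0)), c(1L, 2L))
  expect_equal(ds_vector(c(1, 0), cm, "euclidean"), c(0.75, 0.25))
  expect_equal(ds_vector(c(2, 0), cm, "euclidean"), c(0.5, 0.5))
  # coinciding with a centroid -> that cluster 1, all others 0
  expect_equal(ds_vector(c(4, 0), cm, "euclidean"), c(0, 1))

  dup <- build_cluster_model(rbind(c(1, 1), c(1, 1)), c(1L, 2L))
  expect_error(ds_vector(c(1, 1), dup, "euclidean"), "coincident")
})

test_that("DS values live in [0,1], rows sum to 1, and DS_m grows as d_m shrinks", {
  set.seed(13)
  for (i in 1:50) {
    m <- sample(2:6, 1)
    d <- sample(2:8, 1)
    C <- matrix(runif(m * d, 1, 5), m, d)
    cm <- build_cluster_model(C, seq_len(m), "neuron_weights", weights = C)
    f <- runif(d, 1, 5)
    for (metric in c("cosine", "euclidean")) {
      ds <- ds_vector(f, cm, metric)
      expect_true(all(ds >= 0 & ds <= 1))
      expect_equal(sum(ds), 1, tolerance = 1e-12)
    }
    # monotonicity: moving f toward centroid 1 raises DS_1
    ds0 <- ds_vector(f, cm, "euclidean")
    f2 <- f + 0.9 * (C[1, ] - f)
    ds1 <- ds_vector(f2, cm, "euclidean")
    expect_gt(ds1[1], ds0[1])
  }
})

test_that("DS approaches the zero-distance branch in the limit f -> centroid", {
  cm <- build_cluster_model(rbind(c(1, 0), c(0, 1)), c(1L, 2L))
  eps <- 10^-(3:8)
  vals <- sapply(eps, function(e) {
    ds_vector(c(1, e), cm, "euclidean")[1]
  })
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[length(vals)], 1 - 1e-6)
})

test_that("cosine DS is invariant to positive rescaling of the frame", {
  set.seed(5)
  C <- matrix(runif(12, 1, 3), 4, 3)
  cm <- build_cluster_model(C, 1:4, "neuron_weights", weights = C)
  f <- runif(3, 1, 3)
  expect_equal(ds_vector(f, cm, "cosine"), ds_vector(7.3 * f, cm, "cosine"),
               tolerance = 1e-12)
})

test_that("trajectories are one-hot on constant sequences and rows sum to 1", {
  C <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  cm <- build_cluster_model(C, 1:3, "neuron_weights", weights = C)
  const <- matrix(rep(C[3, ], 10), 10, byrow = TRUE)
  ds <- ds_trajectory(const, cm, "euclidean", smooth_window = 1)
  expect_true(all(ds$scores[, 3] == 1))
  expect_equal(ds$winner, rep(3L, 10))
  expect_length(ds$transitions, 0)

  set.seed(17)
  X <- matrix(runif(90, 1, 2), 30, 3)
  ds2 <- ds_trajectory(X, cm, "cosine", smooth_window = 1)
  expect_equal(rowSums(ds2$scores), rep(1, 30), tolerance = 1e-12)
})

test_that("a two-segment sequence yields exactly one transition and balanced dwell", {
  C <- rbind(c(0, 0), c(10, 10))
  cm <- build_cluster_model(C, 1:2, "neuron_weights", weights = C)
  set.seed(23)
  X <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
             matrix(rnorm(100, 10, 0.3), 50, 2))
  ds <- ds_trajectory(X, cm, "euclidean", smooth_window = 5)
  expect_equal(ds$transitions, 51L)
  expect_equal(ds$per_cluster$dwell_fraction, c(0.5, 0.5))
  expect_equal(sum(ds$per_cluster$dwell_fraction), 1)
})

test_that("the winner mode filter reproduces the hand-traced example", {
  raw <- c(1, 1, 2, 1, 1, 2, 2, 2)
  scores <- diag(2)[raw, ]
  expect_equal(winner_sequence(scores, 1), raw)
  expect_equal(winner_sequence(scores, 3), c(1, 1, 1, 1, 1, 2, 2, 2))
  # argmax ties break to the lowest cluster index
  expect_equal(winner_sequence(matrix(c(0.4, 0.4, 0.2), 1), 1), 1L)
  expect_error(winner_sequence(scores, 4), "odd")
  expect_error(winner_sequence(scores, 9), "exceeds")
})

test_that("transition frames are exactly the winner changes", {
  expect_equal(detect_transitions(c(1, 1, 1, 2, 2)), 4L)
  expect_equal(detect_transitions(rep(3, 10)), integer(0))
  expect_equal(detect_transitions(c(1, 2, 1)), c(2L, 3L))
  expect_error(detect_transitions(integer(0)), "empty")
})

test_that("peak/dwell statistics flag clusters that never win", {
  C <- rbind(c(0, 0), c(10, 10), c(100, 100))
  cm <- build_cluster_model(C, 1:3, "neuron_weights", weights = C)
  X <- matrix(rep(c(0.1, 0.1), 20), 20, byrow = TRUE)
  ds <- ds_trajectory(X, cm, "euclidean", smooth_window = 1)
  st <- ds$per_cluster
  expect_equal(st$dwell_fraction, c(1, 0, 0))
  expect_equal(st$peak_ds[2:3], c(0, 0)) # never wins -> peak 0
  expect_gt(st$peak_ds_all[2], 0) # transparency: all-frames max retained
})

test_that("undefined centroids require a prototype fallback", {
  X <- matrix(runif(20, 1, 2), 10, 2)
  cm <- build_cluster_model(X, rep(1L, 10), n_clusters = 2)
  expect_error(ds_trajectory(X, cm, "euclidean"), "fallback_weights")
  W <- rbind(colMeans(X), c(50, 50))
  ds <- ds_trajectory(X, cm, "euclidean", smooth_window = 1,
                      fallback_weights = W)
  expect_equal(ds$fallback_clusters, 2L)
  expect_equal(ds$per_cluster$dwell_fraction, c(1, 0))
})
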