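test_that("initialization is reproducible and respects its scheme", {
  cfg <- som_config(seed = 11)
  a <- init_som(4, 6, cfg)
  b <- init_som(4, 6, cfg)
  expect_identical(a$weights, b$weights)

  set.seed(3)
  X <- matrix(rnorm(40, mean = 5, sd = 2), 10, 4)
  u <- init_som(5, 4, som_config(seed = 2, init = "uniform"), data = X)
  expect_true(all(sweep(u$weights, 2, apply(X, 2, min)) >= 0))
  expect_true(all(sweep(u$weights, 2, apply(X, 2, max)) <= 0))

  s <- init_som(10, 4, som_config(seed = 2, init = "sample"), data = X)
  expect_equal(sort(apply(s$weights, 1, paste, collapse = ",")),
               sort(apply(X, 1, paste, collapse = ",")))
  expect_error(init_som(11, 4, som_config(init = "sample"), data = X),
               "at least M")
})

test_that("the best matching unit is the nearest weight with lowest-index ties", {
  m <- init_som(2, 2, som_config(seed = 1))
  m$weights <- rbind(c(0, 1), c(1, 1))
  m$metric <- "cosine"
  # cosine distances 1 and 1 - 1/sqrt(2) ~ 0.2929
  expect_equal(find_bmu(c(1, 0), m), 2L)

  m4 <- init_som(4, 3, som_config(seed = 1))
  m4$weights <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(2, 2, 2))
  m4$metric <- "euclidean"
  expect_equal(find_bmu(c(0, 0, 1), m4), 3L)
  # equidistant weights -> lowest index
  tie <- init_som(2, 2, som_config(seed = 1))
  tie$weights <- rbind(c(1, 0), c(0, 1))
  tie$metric <- "euclidean"
  expect_equal(find_bmu(c(0.5, 0.5), tie), 1L)
  expect_error(find_bmu(c(0, 0), m), "zero-norm")
})

test_that("training is bit-deterministic given the seed and a no-op at zero epochs", {
  set.seed(9)
  X <- matrix(runif(200, 1, 2), 50, 4)
  cfg <- som_config(epochs = 10, seed = 21)
  m1 <- train_som(X, 3, "cosine", cfg)
  m2 <- train_som(X, 3, "cosine", cfg)
  expect_identical(m1$weights, m2$weights)

  cfg0 <- som_config(epochs = 0, seed = 21)
  m0 <- train_som(X, 3, "cosine", cfg0)
  expect_identical(m0$weights, init_som(3, 4, cfg0, data = X)$weights)
})

test_that("two well-separated blobs are learned with perfect purity", {
  hits <- 0
  for (s in 1:20) {
    g <- make_gaussian_postures(2, d = 8, separation = 20,
                                n_per_cluster = 50, sd = 0.5, seed = s)
    m <- train_som(g$data, 2, "euclidean", som_config(seed = s))
    a <- assign_clusters(g$data, m)
    if (best_permutation_purity(a, g$labels) == 1) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("assignments reproduce exact-match and purity contracts", {
  m <- init_som(3, 2, som_config(seed = 1))
  m$weights <- rbind(c(1, 1), c(5, 5), c(9, 9))
  m$metric <- "euclidean"
  expect_equal(assign_clusters(m$weights, m), 1:3)
  expect_equal(assign_clusters(rbind(c(5.1, 5)), m), 2L)
})

test_that("quantization error is the mean squared point-to-BMU distance", {
  m <- init_som(2, 2, som_config(seed = 1))
  m$weights <- rbind(c(0, 1), c(sqrt(2) / 2, sqrt(2) / 2))
  m$metric <- "cosine"
  expect_equal(quantization_error(matrix(c(1, 0), 1), m),
               (1 - sqrt(2) / 2)^2, tolerance = 1e-12)
  # every point on a weight -> 0
  m$metric <- "euclidean"
  expect_equal(quantization_error(m$weights, m), 0)
  # duplicating the data leaves the mean unchanged
  X <- matrix(runif(20, 1, 3), 10, 2)
  expect_equal(quantization_error(X, m),
               quantization_error(rbind(X, X), m))
})

test_that("training lowers quantization error relative to initialization", {
  better <- 0
  for (s in 1:20) {
    g <- make_gaussian_postures(3, d = 10, separation = 8,
                                n_per_cluster = 40, sd = 1, seed = s)
    cfg <- som_config(seed = s)
    m0 <- init_som(3, 10, cfg, data = g$data)
    m0$metric <- "euclidean"
    m1 <- train_som(g$data, 3, "euclidean", cfg)
    if (quantization_error(g$data, m1) < quantization_error(g$data, m0)) {
      better <- better + 1
    }
  }
  expect_gt(better, 10) # mean over seeds must improve; here every seed does
})

test_that("a single-neuron map converges into the data range", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(runif(60, 2, 4), 20, 3)
    m <- train_som(X, 1, "euclidean", som_config(seed = s))
    expect_true(all(m$weights >= 2 & m$weights <= 4))
  }
})

test_that("model JSON serialization round-trips weights at full precision", {
  set.seed(5)
  X <- matrix(runif(80, 1, 2), 20, 4)
  m <- train_som(X, 3, "cosine", som_config(epochs = 5, seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  cm <- build_cluster_model(X, assign_clusters(X, m))
  write_som(m, path, centroids = cm$centroids)
  m2 <- read_som(path)
  expect_equal(m2$weights, m$weights, tolerance = 0)
  expect_identical(m2$metric, "cosine")
  expect_equal(m2$centroids, cm$centroids, tolerance = 0)
  expect_equal(m2$config$epochs, 5L)
})
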