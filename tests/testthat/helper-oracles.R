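# Brute-force oracles: deliberately naive per-point loops, kept independent
# of the package's vectorized implementations.

oracle_dist <- function(x, y, metric) {
  if (metric == "cosine") {
    1 - sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
  } else {
    sqrt(sum((x - y)^2))
  }
}

# per-sample silhouette values by direct evaluation of the definitions
oracle_silhouette <- function(X, lab, metric = "euclidean") {
  n <- nrow(X)
  ks <- sort(unique(lab))
  sapply(seq_len(n), function(i) {
    own <- setdiff(which(lab == lab[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(sapply(own, function(j) oracle_dist(X[i, ], X[j, ], metric)))
    b <- min(sapply(setdiff(ks, lab[i]), function(m) {
      mean(sapply(which(lab == m),
                  function(j) oracle_dist(X[i, ], X[j, ], metric)))
    }))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  })
}

oracle_ch <- function(X, lab) {
  ks <- sort(unique(lab))
  M <- length(ks)
  n <- nrow(X)
  g <- colMeans(X)
  between <- 0
  within <- 0
  for (m in ks) {
    idx <- which(lab == m)
    cc <- colMeans(X[idx, , drop = FALSE])
    between <- between + length(idx) * sum((cc - g)^2)
    for (j in idx) within <- within + sum((X[j, ] - cc)^2)
  }
  (between / (M - 1)) / (within / (n - M))
}

oracle_db_mean <- function(X, lab, metric = "euclidean") {
  ks <- sort(unique(lab))
  M <- length(ks)
  cc <- lapply(ks, function(m) colMeans(X[lab == m, , drop = FALSE]))
  spread <- sapply(seq_len(M), function(k) {
    mean(sapply(which(lab == ks[k]),
                function(j) oracle_dist(X[j, ], cc[[k]], metric)))
  })
  total <- 0
  for (k in seq_len(M)) {
    worst <- max(sapply(setdiff(seq_len(M), k), function(k2) {
      (spread[k] + spread[k2]) / oracle_dist(cc[[k]], cc[[k2]], metric)
    }))
    total <- total + worst
  }
  total / M
}

# random labeled dataset with every cluster present and N > M
random_labeled_dataset <- function(seed, n_max = 60, d_max = 8, m_max = 6) {
  set.seed(seed)
  m <- sample(2:m_max, 1)
  n <- sample((m + 2):n_max, 1)
  d <- sample(2:d_max, 1)
  centers <- matrix(runif(m * d, -3, 3), m, d)
  lab <- c(seq_len(m), sample(seq_len(m), n - m, replace = TRUE))
  X <- centers[lab, , drop = FALSE] + matrix(rnorm(n * d), n, d)
  # keep rows away from the origin so the cosine metric is defined
  X <- X + 5
  list(X = X, lab = lab, m = m)
}

# purity of an assignment against true labels under the best permutation
# of cluster identities (exhaustive over k! permutations; k is small here)
best_permutation_purity <- function(assigned, truth) {
  ks <- sort(unique(truth))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  max(vapply(perms(ks), function(p) {
    mean(p[truth] == assigned)
  }, numeric(1)))
}

toy_ab <- function() {
  list(X = rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1)),
       lab = c(1L, 1L, 2L, 2L))
}
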