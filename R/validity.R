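#' Per-sample silhouette values
#'
#' For sample `i` in cluster `m`: `a` is the mean distance to the other
#' `K_m - 1` members of its own cluster, `b` is the smallest mean distance to
#' the members of any other (non-empty) cluster, and the silhouette value is
#' `(b - a) / max(a, b)`, in `[-1, 1]`. Values near 1 mean the sample sits
#' well inside its cluster; near 0, on a boundary; negative, closer to
#' another cluster. Samples in singleton clusters get 0 by convention
#' (their `a` is undefined).
#'
#' @param data Numeric `N x D` matrix.
#' @param clusters A [build_cluster_model()] result.
#' @param metric `"cosine"` or `"euclidean"` (default cosine, the metric the
#'   posture maps are trained with).
#' @return A list of class `silhouette_result`: `a`, `b`, `sc` (per-sample,
#'   length `N`; `a` is `NA` for singletons) and `mean_sc`.
#' @export
silhouette_values <- function(data, clusters, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  data <- as.matrix(data)
  stopifnot(inherits(clusters, "cluster_model"))
  lab <- clusters$assignments
  M <- clusters$n_clusters
  sizes <- clusters$sizes
  if (sum(sizes > 0) < 2) {
    stop("silhouette is undefined with fewer than 2 non-empty clusters",
         call. = FALSE)
  }
  n <- nrow(data)
  D <- .dist_rows(data, data, metric)

  # summed distance from every sample to the members of every cluster
  Z <- matrix(0, n, M)
  Z[cbind(seq_len(n), lab)] <- 1
  S <- D %*% Z # n x M

  a <- ifelse(sizes[lab] > 1, S[cbind(seq_len(n), lab)] / (sizes[lab] - 1),
              NA_real_)
  live <- which(sizes > 0)
  B <- S[, live, drop = FALSE] / rep(sizes[live], each = n)
  own <- match(lab, live)
  B[cbind(seq_len(n), own)] <- Inf # exclude the sample's own cluster
  b <- apply(B, 1, min)
  sc <- ifelse(is.na(a), 0, (b - a) / pmax(a, b))
  sc[is.nan(sc)] <- 0 # a = b = 0: duplicated points across clusters
  structure(list(a = a, b = b, sc = sc, mean_sc = mean(sc)),
            class = "silhouette_result")
}

#' @export
print.silhouette_result <- function(x, ...) {
  cat("Silhouette: mean ", format(x$mean_sc, digits = 4), " over ",
      length(x$sc), " samples (range ",
      format(min(x$sc), digits = 3), " .. ",
      format(max(x$sc), digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Dunn index, centroid variant
#'
#' Ratio of the minimum distance between cluster *centroids* to the maximum
#' intra-cluster pairwise distance (the largest cluster diameter). Higher is
#' better: compact clusters far apart. Note the numerator uses centroids —
#' not the classical minimum over point pairs from different clusters — so
#' this variant is systematically related to, but not equal to, the textbook
#' Dunn index.
#'
#' Singleton clusters have diameter 0 and simply cannot set the denominator;
#' if every cluster is a singleton the denominator is 0 and the index is
#' returned as `Inf` with `degenerate = TRUE`.
#'
#' @inheritParams silhouette_values
#' @return A list of class `dunn_index`: `value`, `d_cmin` (minimum centroid
#'   separation), `d_max` (maximum cluster diameter), `degenerate`.
#' @export
dunn_index <- function(data, clusters, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  data <- as.matrix(data)
  stopifnot(inherits(clusters, "cluster_model"))
  lab <- clusters$assignments
  live <- which(clusters$sizes > 0)
  if (length(live) < 2) {
    stop("Dunn index needs at least 2 non-empty clusters", call. = FALSE)
  }
  C <- clusters$centroids[live, , drop = FALSE]
  dc <- .dist_rows(C, C, metric)
  d_cmin <- min(dc[upper.tri(dc)])

  d_max <- 0
  for (m in live) {
    idx <- which(lab == m)
    if (length(idx) < 2) next
    dm <- .dist_rows(data[idx, , drop = FALSE], data[idx, , drop = FALSE],
                     metric)
    d_max <- max(d_max, max(dm))
  }
  degenerate <- d_max <= 0
  structure(
    list(value = if (degenerate) Inf else d_cmin / d_max,
         d_cmin = d_cmin, d_max = d_max, degenerate = degenerate),
    class = "dunn_index"
  )
}

#' @export
print.dunn_index <- function(x, ...) {
  cat("Dunn index (centroid variant): ", format(x$value, digits = 4),
      "  [min centroid sep ", format(x$d_cmin, digits = 4),
      ", max diameter ", format(x$d_max, digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Davies-Bouldin index
#'
#' For each cluster, the mean distance of its members to its centroid is
#' computed; every cluster pair is scored by the sum of those two spreads
#' divided by the centroid separation; each cluster keeps its worst pairing.
#' `variant = "paper_sum"` (default) returns the plain *sum* of those maxima
#' over clusters; `variant = "mean"` divides by `M` (the classical form,
#' matching common reference implementations). Over a fixed `M` the two are
#' proportional and rank clusterings identically. Lower is better.
#'
#' @inheritParams silhouette_values
#' @param variant `"paper_sum"` or `"mean"`.
#' @return A list of class `db_index`: `value`, `variant`, `per_cluster`
#'   (each cluster's worst pairing), `degenerate` (`TRUE` when two scored
#'   centroids coincide).
#' @export
davies_bouldin <- function(data, clusters, metric = c("cosine", "euclidean"),
                           variant = c("paper_sum", "mean")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  data <- as.matrix(data)
  stopifnot(inherits(clusters, "cluster_model"))
  lab <- clusters$assignments
  live <- which(clusters$sizes > 0)
  if (length(live) < 2) {
    stop("Davies-Bouldin needs at least 2 non-empty clusters", call. = FALSE)
  }
  C <- clusters$centroids[live, , drop = FALSE]
  spread <- vapply(seq_along(live), function(k) {
    idx <- which(lab == live[k])
    mean(.dist_rows(data[idx, , drop = FALSE], C[k, , drop = FALSE],
                    metric)[, 1])
  }, numeric(1))
  dc <- .dist_rows(C, C, metric)
  degenerate <- any(dc[upper.tri(dc)] < .EPS)
  R <- outer(spread, spread, "+") / dc
  diag(R) <- -Inf
  per_cluster <- apply(R, 1, max)
  total <- sum(per_cluster)
  structure(
    list(value = if (variant == "paper_sum") total else total / length(live),
         variant = variant,
         per_cluster = setNames(per_cluster, live),
         degenerate = degenerate),
    class = "db_index"
  )
}

#' @export
print.db_index <- function(x, ...) {
  cat("Davies-Bouldin (", x$variant, "): ", format(x$value, digits = 4),
      if (x$degenerate) "  [degenerate: coincident centroids]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Calinski-Harabasz index
#'
#' The variance-ratio criterion: between-cluster dispersion over
#' within-cluster dispersion,
#' `CH = [sum_m K_m ||cc_m - c||^2 / (M-1)] / [sum_m sum_k ||f_k - cc_m||^2 / (N-M)]`,
#' always with Euclidean norms. Higher is better; there is no absolute
#' cutoff, so in a scan over candidate cluster counts one looks for a peak
#' or a sharp elbow.
#'
#' @inheritParams silhouette_values
#' @return A single nonnegative number (`Inf` with a warning when the
#'   within-cluster dispersion is zero).
#' @export
calinski_harabasz <- function(data, clusters) {
  data <- as.matrix(data)
  stopifnot(inherits(clusters, "cluster_model"))
  lab <- clusters$assignments
  n <- nrow(data)
  live <- which(clusters$sizes > 0)
  M <- length(live)
  if (M < 2) stop("Calinski-Harabasz needs at least 2 non-empty clusters",
                  call. = FALSE)
  if (n <= M) stop("Calinski-Harabasz requires N > M", call. = FALSE)
  g <- clusters$global_centroid
  between <- sum(vapply(live, function(m) {
    clusters$sizes[m] * sum((clusters$centroids[m, ] - g)^2)
  }, numeric(1)))
  within <- sum(vapply(live, function(m) {
    idx <- which(lab == m)
    sum(sweep(data[idx, , drop = FALSE], 2, clusters$centroids[m, ])^2)
  }, numeric(1)))
  if (within < .EPS^2) {
    warning("zero within-cluster dispersion; CH is infinite", call. = FALSE)
    return(Inf)
  }
  (between / (M - 1)) / (within / (n - M))
}

#' Assemble the full index report for one clustering
#'
#' One record per cluster count: mean silhouette, centroid-variant Dunn,
#' Davies-Bouldin (sum form by default), Calinski-Harabasz, and the map's
#' quantization error, plus degeneracy flags (empty clusters, singletons,
#' coincident centroids). All distance-flexible indices use the map's
#' training metric; CH is Euclidean by definition.
#'
#' @param data Numeric `N x D` matrix.
#' @param clusters A [build_cluster_model()] result derived from `som`'s
#'   assignments.
#' @param som The trained `som_model` (supplies the metric and the
#'   quantization error).
#' @param db_variant Passed to [davies_bouldin()].
#' @return A list of class `index_report`: `k`, `sc_mean`, `dunn`, `dbi`,
#'   `dbi_variant`, `ch`, `qe`, `flags`. Indices that are undefined for the
#'   clustering at hand are `NA` with the reason recorded in `flags`.
#' @export
compute_report <- function(data, clusters, som,
                           db_variant = c("paper_sum", "mean")) {
  db_variant <- match.arg(db_variant)
  stopifnot(inherits(clusters, "cluster_model"), inherits(som, "som_model"))
  metric <- if (is.na(som$metric)) "euclidean" else som$metric
  flags <- list(empty_clusters = which(clusters$empty),
                singleton_clusters = which(clusters$sizes == 1L),
                degenerate = character(0))

  sil <- tryCatch(silhouette_values(data, clusters, metric),
                  error = function(e) e)
  if (inherits(sil, "error")) {
    sc_mean <- NA_real_
    flags$degenerate <- c(flags$degenerate, "silhouette")
  } else sc_mean <- sil$mean_sc

  dn <- tryCatch(dunn_index(data, clusters, metric), error = function(e) e)
  if (inherits(dn, "error")) {
    dunn <- NA_real_
    flags$degenerate <- c(flags$degenerate, "dunn")
  } else {
    dunn <- dn$value
    if (dn$degenerate) flags$degenerate <- c(flags$degenerate, "dunn")
  }

  db <- tryCatch(davies_bouldin(data, clusters, metric, db_variant),
                 error = function(e) e)
  if (inherits(db, "error")) {
    dbi <- NA_real_
    flags$degenerate <- c(flags$degenerate, "davies_bouldin")
  } else {
    dbi <- db$value
    if (db$degenerate) flags$degenerate <- c(flags$degenerate, "davies_bouldin")
  }

  ch <- tryCatch(suppressWarnings(calinski_harabasz(data, clusters)),
                 error = function(e) e)
  if (inherits(ch, "error")) {
    ch <- NA_real_
    flags$degenerate <- c(flags$degenerate, "calinski_harabasz")
  }

  structure(
    list(k = clusters$n_clusters, sc_mean = sc_mean, dunn = dunn,
         dbi = dbi, dbi_variant = db_variant, ch = ch,
         qe = quantization_error(data, som), flags = flags),
    class = "index_report"
  )
}

#' @export
print.index_report <- function(x, ...) {
  cat(sprintf("k = %d | SC %.4f | DI %.4f | DBI(%s) %.4f | CH %.2f | QE %.5f\n",
              x$k, x$sc_mean, x$dunn, x$dbi_variant, x$dbi, x$ch, x$qe))
  if (length(x$flags$empty_clusters)) {
    cat("  empty clusters:", paste(x$flags$empty_clusters, collapse = ","), "\n")
  }
  if (length(x$flags$degenerate)) {
    cat("  degenerate:", paste(x$flags$degenerate, collapse = ","), "\n")
  }
  invisible(x)
}

#' One-row data frame view of an index report
#' @param x An `index_report`.
#' @return A one-row `data.frame` with columns `k, sc_mean, dunn, dbi,
#'   dbi_variant, ch, qe, flags`.
#' @export
as.data.frame.index_report <- function(x, ...) {
  data.frame(k = x$k, sc_mean = x$sc_mean, dunn = x$dunn, dbi = x$dbi,
             dbi_variant = x$dbi_variant, ch = x$ch, qe = x$qe,
             flags = paste(c(
               if (length(x$flags$empty_clusters))
                 paste0("empty:", paste(x$flags$empty_clusters, collapse = "+")),
               if (length(x$flags$degenerate))
                 paste0("degenerate:", paste(x$flags$degenerate, collapse = "+"))
             ), collapse = ";"),
             stringsAsFactors = FALSE)
}
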