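#' Build a cluster model from data and assignments
#'
#' Bundles everything the validity indices and the discriminant score need:
#' per-cluster centroids, sizes, the global centroid, and bookkeeping for
#' empty clusters. Centroids are either the arithmetic means of the assigned
#' rows (`source = "data_means"`, the default, matching the centroid notation
#' the indices are written in) or externally supplied prototype vectors such
#' as trained neuron weights (`source = "neuron_weights"`).
#'
#' Empty clusters are retained, not dropped: a self-organizing map routinely
#' leaves "dead" neurons that never win, and the indices must know about them.
#' An empty cluster's data-mean centroid is undefined and stored as `NA`;
#' downstream scores either skip it or fall back to the neuron weight (see
#' [ds_trajectory()]).
#'
#' @param data Numeric matrix, one row per sample.
#' @param assignments Integer vector of cluster indices in `1..n_clusters`.
#' @param source `"data_means"` or `"neuron_weights"`.
#' @param weights `M x D` matrix of prototype vectors, required when
#'   `source = "neuron_weights"` (also used to fix `M`).
#' @param n_clusters Number of clusters `M`; defaults to `nrow(weights)` or
#'   `max(assignments)`.
#' @return An object of class `cluster_model`: a list with elements
#'   `n_clusters`, `assignments`, `centroids` (`M x D`, `NA` rows for empty
#'   data-mean clusters), `sizes`, `global_centroid`, `source`, `empty`
#'   (logical per cluster).
#' @examples
#' x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' cm <- build_cluster_model(x, c(1, 1, 2, 2))
#' cm$centroids
#' cm$sizes
#' @export
build_cluster_model <- function(data, assignments,
                                source = c("data_means", "neuron_weights"),
                                weights = NULL, n_clusters = NULL) {
  source <- match.arg(source)
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("data must be a finite numeric matrix", call. = FALSE)
  }
  n <- nrow(data)
  assignments <- as.integer(assignments)
  if (length(assignments) != n) {
    stop("assignments length (", length(assignments),
         ") must equal nrow(data) (", n, ")", call. = FALSE)
  }
  if (source == "neuron_weights") {
    if (is.null(weights)) {
      stop("source = \"neuron_weights\" requires `weights`", call. = FALSE)
    }
    weights <- as.matrix(weights)
    if (ncol(weights) != ncol(data)) {
      stop("weights dimension mismatch", call. = FALSE)
    }
    if (is.null(n_clusters)) n_clusters <- nrow(weights)
    if (nrow(weights) != n_clusters) {
      stop("nrow(weights) must equal n_clusters", call. = FALSE)
    }
  }
  if (is.null(n_clusters)) n_clusters <- max(assignments)
  if (any(assignments < 1L) || any(assignments > n_clusters)) {
    stop("assignment index outside 1..", n_clusters, call. = FALSE)
  }

  sizes <- tabulate(assignments, nbins = n_clusters)
  empty <- sizes == 0L

  if (source == "data_means") {
    centroids <- matrix(NA_real_, n_clusters, ncol(data))
    sums <- rowsum(data, group = assignments) # one row per non-empty cluster
    idx <- as.integer(rownames(sums))
    centroids[idx, ] <- sums / sizes[idx]
  } else {
    centroids <- weights
  }

  structure(
    list(n_clusters = n_clusters,
         assignments = assignments,
         centroids = centroids,
         sizes = sizes,
         global_centroid = colMeans(data),
         source = source,
         empty = empty),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Cluster model: ", x$n_clusters, " clusters, ",
      length(x$assignments), " samples, D = ", ncol(x$centroids),
      " (centroids: ", x$source, ")\n", sep = "")
  cat("  sizes:", paste(x$sizes, collapse = ", "))
  if (any(x$empty)) cat("  [empty:", paste(which(x$empty), collapse = ","), "]")
  cat("\n")
  invisible(x)
}
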