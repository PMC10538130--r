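#' Discriminant score of one frame against every cluster
#'
#' The per-frame, per-cluster membership score. With `d_m` the distance from
#' the frame to centroid `m` under `metric`, the score of cluster `m` is the
#' normalized inverse distance
#' `DS_m = (1 / d_m) / sum_m' (1 / d_m')`,
#' and when the frame coincides with a centroid (`d_m = 0`) that cluster
#' scores exactly 1 and all others 0. Scores lie in `[0, 1]` and sum to 1
#' over clusters: 1 means perfect similarity to a centroid, values near
#' `1/M` mean the frame is ambiguous between clusters. The denominator
#' carries the dispersion information: a frame moderately close to one
#' centroid still scores high if every other centroid is far away.
#'
#' @param f Numeric feature vector (one skeleton frame).
#' @param clusters A [build_cluster_model()] result with all centroids
#'   defined.
#' @param metric `"cosine"` or `"euclidean"`.
#' @return Numeric vector of length `M` summing to 1.
#' @examples
#' cm <- build_cluster_model(rbind(c(0, 0), c(4, 0)), c(1, 2))
#' ds_vector(c(1, 0), cm, "euclidean") # distances 1 and 3 -> 0.75, 0.25
#' @export
ds_vector <- function(f, clusters, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(clusters, "cluster_model"))
  C <- clusters$centroids
  if (anyNA(C)) {
    stop("undefined centroid(s): cluster(s) ",
         paste(which(apply(is.na(C), 1, any)), collapse = ", "),
         " are empty; supply prototype centroids instead", call. = FALSE)
  }
  d <- .dist_rows(matrix(f, nrow = 1), C, metric)[1, ]
  .ds_from_dist(d)
}

.ds_from_dist <- function(d) {
  hit <- which(d <= 0)
  if (length(hit) > 1) {
    stop("frame is at zero distance from ", length(hit),
         " centroids (coincident centroids)", call. = FALSE)
  }
  if (length(hit) == 1) {
    out <- numeric(length(d))
    out[hit] <- 1
    return(out)
  }
  inv <- 1 / d
  inv / sum(inv)
}

#' Discriminant-score trajectory of a posture sequence
#'
#' Evaluates [ds_vector()] for every frame, then derives the temporal
#' structure the score is designed to expose: the per-frame winning cluster
#' (mode-smoothed to suppress single-frame chatter), the transition frames
#' where the winner changes — visible in the trajectories as a steep drop of
#' the outgoing cluster's score against a simultaneous rise of the incoming
#' one — and per-cluster peak and dwell statistics.
#'
#' Clusters whose data-mean centroid is undefined (neurons that never won
#' during assignment) fall back to the prototype in `fallback_weights`, so
#' the score stays defined over all `M` clusters; such clusters typically
#' trace a flat low trajectory and never win.
#'
#' @param seq A [posture_sequence()] or a numeric `T x D` matrix in temporal
#'   order.
#' @param clusters A [build_cluster_model()] result.
#' @param metric `"cosine"` or `"euclidean"`.
#' @param smooth_window Odd window (frames) for the winner mode filter;
#'   default 5 (a third of a second at 15 fps). 1 disables smoothing.
#' @param fallback_weights Optional `M x D` prototype matrix (e.g. trained
#'   neuron weights) substituted for undefined centroids.
#' @return An object of class `ds_matrix`: list with `scores` (`T x M`, rows
#'   sum to 1), `metric`, `winner` (smoothed), `winner_raw`, `smooth_window`,
#'   `transitions` (frame indices where the smoothed winner changes),
#'   `per_cluster` (data frame: `cluster`, `peak_ds` — max score over frames
#'   the cluster wins, 0 if it never wins —, `peak_ds_all` — max over all
#'   frames —, `dwell_fraction`), and `fallback_clusters`.
#' @export
ds_trajectory <- function(seq, clusters, metric = c("cosine", "euclidean"),
                          smooth_window = 5, fallback_weights = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(clusters, "cluster_model"))
  X <- if (inherits(seq, "posture_sequence")) seq$frames else as.matrix(seq)
  if (nrow(X) == 0) stop("empty sequence", call. = FALSE)

  C <- clusters$centroids
  fallback <- integer(0)
  if (anyNA(C)) {
    fallback <- which(apply(is.na(C), 1, any))
    if (is.null(fallback_weights)) {
      stop("undefined centroid(s) for cluster(s) ",
           paste(fallback, collapse = ", "),
           "; supply fallback_weights (e.g. the neuron weights)",
           call. = FALSE)
    }
    fallback_weights <- as.matrix(fallback_weights)
    C[fallback, ] <- fallback_weights[fallback, , drop = FALSE]
  }

  D <- .dist_rows(X, C, metric)
  scores <- t(apply(D, 1, function(d) {
    tryCatch(.ds_from_dist(d), error = function(e) {
      stop(conditionMessage(e), call. = FALSE)
    })
  }))
  scores <- matrix(scores, nrow = nrow(X))

  winner_raw <- max.col(scores, ties.method = "first")
  winner <- winner_sequence(scores, smooth_window)
  out <- structure(
    list(scores = scores, metric = metric,
         winner = winner, winner_raw = winner_raw,
         smooth_window = smooth_window,
         transitions = detect_transitions(winner),
         per_cluster = NULL,
         fallback_clusters = fallback),
    class = "ds_matrix"
  )
  out$per_cluster <- peak_dwell_stats(out)
  out
}

#' @export
print.ds_matrix <- function(x, ...) {
  cat("Discriminant-score trajectory: ", nrow(x$scores), " frames x ",
      ncol(x$scores), " clusters (", x$metric, "), ",
      length(x$transitions), " transitions\n", sep = "")
  print(x$per_cluster, row.names = FALSE)
  invisible(x)
}

#' Per-frame winning cluster with mode smoothing
#'
#' Argmax per frame (ties to the lowest cluster index), then a centered
#' sliding-mode filter with edge replication. A window of 1 means no
#' smoothing. Smoothing removes single-frame winner flips caused by jitter
#' without displacing genuine posture transitions by more than half the
#' window.
#'
#' @param scores `T x M` matrix of discriminant scores (or any row scores).
#' @param smooth_window Odd positive integer `<= T`.
#' @return Integer vector of winning cluster indices, length `T`.
#' @export
winner_sequence <- function(scores, smooth_window = 1) {
  scores <- as.matrix(scores)
  tt <- nrow(scores)
  if (smooth_window %% 2 != 1 || smooth_window < 1) {
    stop("smooth_window must be an odd positive integer", call. = FALSE)
  }
  if (smooth_window > tt) {
    stop("smooth_window (", smooth_window, ") exceeds sequence length (",
         tt, ")", call. = FALSE)
  }
  w <- max.col(scores, ties.method = "first")
  if (smooth_window == 1) return(w)
  half <- (smooth_window - 1) %/% 2
  padded <- c(rep(w[1], half), w, rep(w[tt], half))
  vapply(seq_len(tt), function(i) {
    win <- padded[i:(i + 2 * half)]
    tab <- tabulate(win, nbins = max(win))
    which.max(tab) # ties to the lowest index
  }, integer(1))
}

#' Frames at which the winning cluster changes
#'
#' @param winner Integer vector of per-frame winning clusters.
#' @return Increasing integer vector of frame indices `t >= 2` with
#'   `winner[t] != winner[t - 1]` (the first frame of each new regime);
#'   empty when the winner never changes.
#' @export
detect_transitions <- function(winner) {
  if (length(winner) == 0) stop("empty winner sequence", call. = FALSE)
  which(diff(winner) != 0) + 1L
}

#' Per-cluster peak and dwell statistics
#'
#' For each cluster: the peak score over the frames in which it wins (0 if
#' it never wins — transient or dead clusters), the peak over *all* frames
#' (for transparency: a cluster can score moderately on frames it loses),
#' and the dwell fraction — the share of frames it wins. Low peak or low
#' dwell marks a cluster that does not correspond to a sustained, well
#' discriminated posture.
#'
#' @param ds A `ds_matrix` from [ds_trajectory()].
#' @return A data frame with columns `cluster`, `peak_ds`, `peak_ds_all`,
#'   `dwell_fraction` (dwell fractions sum to 1).
#' @export
peak_dwell_stats <- function(ds) {
  stopifnot(inherits(ds, "ds_matrix"))
  scores <- ds$scores
  winner <- ds$winner
  M <- ncol(scores)
  tt <- nrow(scores)
  peak <- numeric(M)
  dwell <- numeric(M)
  for (m in seq_len(M)) {
    wins <- winner == m
    dwell[m] <- sum(wins) / tt
    peak[m] <- if (any(wins)) max(scores[wins, m]) else 0
  }
  data.frame(cluster = seq_len(M), peak_ds = peak,
             peak_ds_all = apply(scores, 2, max),
             dwell_fraction = dwell)
}
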