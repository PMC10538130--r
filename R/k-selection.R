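#' Criteria for the peak-based cluster-count rule
#'
#' A candidate cluster count `k` passes when every one of its clusters
#' corresponds to a sustained, well-discriminated posture: the per-cluster
#' peak discriminant score must reach `theta_peak` and the per-cluster dwell
#' fraction must reach `theta_dwell` (the dwell check is skipped when dwell
#' data are unavailable, e.g. when scoring a printed peak table).
#'
#' `theta_peak = 0.5` is the default: a cluster whose best frame is more
#' similar to some other centroid than to its own is not a credible posture.
#' `rule` picks among the passing candidates: `"largest_passing_k"` (default)
#' prefers the richest posture vocabulary that remains well discriminated —
#' avoiding the omission of rarer key postures — while `"best_min_peak"`
#' takes the candidate whose weakest cluster is strongest.
#'
#' @param theta_peak Minimum per-cluster peak discriminant score, in (0, 1).
#' @param theta_dwell Minimum per-cluster dwell fraction, in (0, 1).
#' @param rule `"largest_passing_k"` or `"best_min_peak"`.
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(theta_peak = 0.5, theta_dwell = 0.05,
                               rule = c("largest_passing_k", "best_min_peak")) {
  rule <- match.arg(rule)
  if (!(theta_peak > 0 && theta_peak < 1)) {
    stop("theta_peak must lie in (0, 1)", call. = FALSE)
  }
  if (!(theta_dwell > 0 && theta_dwell < 1)) {
    stop("theta_dwell must lie in (0, 1)", call. = FALSE)
  }
  structure(list(theta_peak = theta_peak, theta_dwell = theta_dwell,
                 rule = rule),
            class = "selection_criteria")
}

#' Scan candidate cluster counts
#'
#' For each candidate `k`, trains an independently seeded map
#' (`seed = config$seed + k`), derives the data-mean cluster model from its
#' assignments, computes the full validity-index report, and evaluates the
#' discriminant-score trajectory. Everything is deterministic given the
#' base seed.
#'
#' @param data Numeric `T x D` matrix in temporal order (rows are frames),
#'   or a [posture_sequence()].
#' @param k_candidates Integer vector of candidate cluster counts (each
#'   `>= 2` and `< N`).
#' @param metric `"cosine"` or `"euclidean"` — used for training, winner
#'   matching, the metric-flexible indices, and the discriminant score.
#' @param config Base [som_config()]; its seed seeds the whole scan.
#' @param smooth_window Winner smoothing window for [ds_trajectory()].
#' @return A list of class `k_scan`: per candidate, a record with elements
#'   `k`, `som`, `clusters`, `report` and `ds`.
#' @seealso [recommend_k()]
#' @export
scan_k <- function(data, k_candidates, metric = c("cosine", "euclidean"),
                   config = som_config(), smooth_window = 5) {
  metric <- match.arg(metric)
  X <- if (inherits(data, "posture_sequence")) data$frames else as.matrix(data)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (any(k_candidates < 2)) stop("candidates must be >= 2", call. = FALSE)
  if (any(k_candidates >= nrow(X))) {
    stop("candidate k must be smaller than the number of frames (",
         nrow(X), ")", call. = FALSE)
  }
  records <- lapply(k_candidates, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    som <- train_som(X, k, metric, cfg)
    assignments <- assign_clusters(X, som)
    clusters <- build_cluster_model(X, assignments, "data_means",
                                    n_clusters = k)
    list(k = k,
         som = som,
         clusters = clusters,
         report = compute_report(X, clusters, som),
         ds = ds_trajectory(X, clusters, metric,
                            smooth_window = smooth_window,
                            fallback_weights = som$weights))
  })
  names(records) <- as.character(k_candidates)
  structure(records, class = "k_scan")
}

#' @export
print.k_scan <- function(x, ...) {
  cat("Cluster-count scan over k = {",
      paste(vapply(x, function(r) r$k, integer(1)), collapse = ", "), "}\n",
      sep = "")
  for (r in x) print(r$report)
  invisible(x)
}

#' Recommend a cluster count from peak/dwell statistics
#'
#' Applies the peak-based rule to a [scan_k()] result, or directly to
#' per-candidate peak vectors (e.g. a published table of per-cluster maximum
#' discriminant scores). A candidate passes when its weakest cluster still
#' peaks at `theta_peak` or above — and, when dwell data are present, when
#' every cluster wins at least a `theta_dwell` share of frames. The full
#' audit trail (per-candidate minimum peak, failing clusters, reasons) is
#' returned alongside the choice.
#'
#' When called on a `k_scan`, the recommendation also records the
#' Calinski-Harabasz argmax over the candidates and flags disagreement with
#' the discriminant-score choice rather than resolving it.
#'
#' @param x A `k_scan`, or a named list mapping each candidate `k` to either
#'   a numeric vector of per-cluster peak scores or a data frame with
#'   columns `peak_ds` (and optionally `dwell_fraction`).
#' @param criteria A [selection_criteria()].
#' @return A list of class `k_recommendation`: `chosen_k` (`NA` when no
#'   candidate passes), `criteria`, `per_k` (audit data frame with columns
#'   `k`, `pass`, `min_peak`, `min_dwell`, `failing_clusters`, `reason`),
#'   and, for `k_scan` input, `ch_argmax` and `ch_agrees`.
#' @examples
#' peaks <- list(`3` = c(0.81, 0.97, 0.78), `4` = c(0.71, 0.90, 0.78, 0.60),
#'               `5` = c(0.61, 0.44, 0.84, 0.63, 0.64),
#'               `6` = c(0.66, 0.82, 0.70, 0.59, 0.32, 0.39))
#' recommend_k(peaks)
#' @export
recommend_k <- function(x, criteria = selection_criteria()) {
  stopifnot(inherits(criteria, "selection_criteria"))
  scan <- NULL
  if (inherits(x, "k_scan")) {
    scan <- x
    x <- lapply(scan, function(r) r$ds$per_cluster)
  }
  if (length(x) == 0) stop("no candidates supplied", call. = FALSE)
  ks <- as.integer(names(x))
  if (anyNA(ks)) stop("candidates must be named by their k", call. = FALSE)

  rows <- lapply(seq_along(x), function(i) {
    entry <- x[[i]]
    if (is.data.frame(entry)) {
      peaks <- entry$peak_ds
      dwells <- entry$dwell_fraction
    } else {
      peaks <- as.numeric(entry)
      dwells <- NULL
    }
    fail_peak <- which(peaks < criteria$theta_peak)
    fail_dwell <- if (is.null(dwells)) integer(0) else
      which(dwells < criteria$theta_dwell)
    failing <- sort(union(fail_peak, fail_dwell))
    reason <- paste(c(
      if (length(fail_peak))
        paste0("peak<", criteria$theta_peak, ": cluster ",
               paste(fail_peak, collapse = "+")),
      if (length(fail_dwell))
        paste0("dwell<", criteria$theta_dwell, ": cluster ",
               paste(fail_dwell, collapse = "+"))
    ), collapse = "; ")
    data.frame(k = ks[i],
               pass = length(failing) == 0,
               min_peak = min(peaks),
               min_dwell = if (is.null(dwells)) NA_real_ else min(dwells),
               failing_clusters = paste(failing, collapse = ","),
               reason = if (nzchar(reason)) reason else "ok",
               stringsAsFactors = FALSE)
  })
  per_k <- do.call(rbind, rows)
  per_k <- per_k[order(per_k$k), , drop = FALSE]

  passing <- per_k$k[per_k$pass]
  chosen <- if (length(passing) == 0) {
    NA_integer_
  } else if (criteria$rule == "largest_passing_k") {
    max(passing)
  } else {
    pk <- per_k[per_k$pass, , drop = FALSE]
    pk$k[which.max(pk$min_peak)]
  }

  out <- list(chosen_k = chosen, criteria = criteria, per_k = per_k)
  if (!is.null(scan)) {
    ch <- vapply(scan, function(r) r$report$ch, numeric(1))
    ch_ok <- is.finite(ch)
    out$ch_argmax <- if (any(ch_ok)) {
      as.integer(names(scan)[ch_ok][which.max(ch[ch_ok])])
    } else NA_integer_
    out$ch_agrees <- identical(out$ch_argmax, chosen)
  }
  structure(out, class = "k_recommendation")
}

#' @export
print.k_recommendation <- function(x, ...) {
  if (is.na(x$chosen_k)) {
    cat("Recommended cluster count: none passing (theta_peak = ",
        x$criteria$theta_peak, ")\n", sep = "")
  } else {
    cat("Recommended cluster count: ", x$chosen_k, " (rule: ",
        x$criteria$rule, ", theta_peak = ", x$criteria$theta_peak, ")\n",
        sep = "")
  }
  print(x$per_k, row.names = FALSE)
  if (!is.null(x$ch_argmax)) {
    cat("Calinski-Harabasz argmax: ", x$ch_argmax,
        if (isTRUE(x$ch_agrees)) " (agrees)" else " (disagrees)", "\n",
        sep = "")
  }
  invisible(x)
}

#' Worked example: peak discriminant scores from a pick-and-place recording
#'
#' Per-cluster maximum discriminant scores reported for a recorded
#' pick-walk-place activity, for maps of 3-6 clusters trained with the
#' cosine metric: one table for the activity the map was trained on
#' (`training`) and one for an unseen related activity (`unseen`). Cluster
#' entries are named by the semantic posture each cluster was identified
#' with; "unknown" marks neurons that never won. These tables are the worked
#' input for [recommend_k()]: at the default threshold the 5- and 6-cluster
#' maps fail on their weakest clusters and the largest passing count is 4.
#'
#' @return A list with elements `training` and `unseen`, each a named list
#'   mapping the candidate `k` (`"3".."6"`) to a named numeric vector of
#'   per-cluster peak scores.
#' @examples
#' recommend_k(pick_place_peaks()$training)
#' @export
pick_place_peaks <- function() {
  list(
    training = list(
      `3` = c(walking = 0.81, picking = 0.97, walking_extended_hands = 0.78),
      `4` = c(walking = 0.71, picking = 0.90, walking_extended_hands = 0.78,
              placing = 0.60),
      `5` = c(walking = 0.61, squatting = 0.44, picking = 0.84,
              walking_extended_hands = 0.63, placing = 0.64),
      `6` = c(walking = 0.66, picking = 0.82, walking_extended_hands = 0.70,
              placing = 0.59, unknown_1 = 0.32, unknown_2 = 0.39)
    ),
    unseen = list(
      `3` = c(walking = 0.60, picking = 0.84, walking_extended_hands = 0.65),
      `4` = c(walking = 0.59, picking = 0.44, walking_extended_hands = 0.56,
              placing = 0.68),
      `5` = c(walking = 0.54, squatting = 0.43, picking = 0.38,
              walking_extended_hands = 0.42, placing = 0.65),
      `6` = c(walking = 0.48, picking = 0.32, walking_extended_hands = 0.41,
              placing = 0.56, unknown_1 = 0.53, unknown_2 = 0.42)
    )
  )
}
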