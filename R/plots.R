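#' Plot a discriminant-score trajectory
#'
#' One line per cluster over frames; steep crossings mark posture
#' transitions (drawn as dashed verticals).
#'
#' @param ds A `ds_matrix` from [ds_trajectory()].
#' @return A ggplot object.
#' @export
plot_ds_trajectory <- function(ds) {
  stopifnot(inherits(ds, "ds_matrix"))
  M <- ncol(ds$scores)
  df <- data.frame(
    frame = rep(seq_len(nrow(ds$scores)), M),
    cluster = factor(rep(seq_len(M), each = nrow(ds$scores))),
    ds = as.vector(ds$scores)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$ds,
                                        colour = .data$cluster)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "frame", y = "discriminant score",
                  colour = "cluster") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (length(ds$transitions) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = ds$transitions,
                                 linetype = "dashed", colour = "grey50",
                                 linewidth = 0.3)
  }
  p
}

#' Plot validity indices across candidate cluster counts
#'
#' @param scan A `k_scan` from [scan_k()].
#' @return A ggplot object, one facet per index.
#' @export
plot_index_profile <- function(scan) {
  stopifnot(inherits(scan, "k_scan"))
  rep_df <- do.call(rbind, lapply(scan, function(r) as.data.frame(r$report)))
  long <- data.frame(
    k = rep(rep_df$k, 5),
    index = rep(c("silhouette", "Dunn", "Davies-Bouldin",
                  "Calinski-Harabasz", "quantization error"),
                each = nrow(rep_df)),
    value = c(rep_df$sc_mean, rep_df$dunn, rep_df$dbi, rep_df$ch, rep_df$qe)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "number of clusters", y = NULL)
}

#' Sorted per-cluster silhouette panels
#'
#' The classic silhouette diagnostic: per cluster, the sorted per-sample
#' silhouette values, with the overall mean drawn as a dashed line.
#'
#' @param sil A `silhouette_result` from [silhouette_values()].
#' @param clusters The matching [build_cluster_model()] result.
#' @return A ggplot object.
#' @export
plot_silhouette <- function(sil, clusters) {
  stopifnot(inherits(sil, "silhouette_result"),
            inherits(clusters, "cluster_model"))
  lab <- clusters$assignments
  ord <- order(lab, -sil$sc)
  df <- data.frame(pos = seq_along(ord),
                   sc = sil$sc[ord],
                   cluster = factor(lab[ord]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$sc,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = sil$mean_sc, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "silhouette value", fill = "cluster")
}
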