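#' Training configuration for a 1-D self-organizing map
#'
#' The map is a chain of `M` output neurons, so the neuron count equals the
#' cluster count. Training is online: each epoch presents every sample once
#' (optionally shuffled); the winning neuron and its chain neighbours move
#' toward the sample by the additive Kohonen rule. Learning rate and the
#' Gaussian neighbourhood radius decay exponentially from their initial to
#' final values over the total number of presentation steps.
#'
#' @param epochs Number of passes over the data (default 50).
#' @param lr0,lr_final Initial/final learning rate (defaults 0.5, 0.01);
#'   `lr0 >= lr_final > 0`.
#' @param sigma0,sigma_final Initial/final neighbourhood radius in
#'   neuron-index units. `sigma0 = NULL` (default) resolves to `max(M/2,
#'   sigma_final)` at training time; `sigma_final` defaults to 0.5 so the
#'   neighbourhood collapses to essentially the winner by the end.
#' @param init Weight initialization: `"uniform"` (i.i.d. on the data's
#'   per-dimension range), `"gaussian"` (per-dimension data mean/sd), or
#'   `"sample"` (M distinct data rows).
#' @param seed RNG seed; training is fully reproducible given the seed.
#' @param shuffle Shuffle presentation order each epoch (default `TRUE`).
#' @return A list of class `som_config`.
#' @export
som_config <- function(epochs = 50, lr0 = 0.5, lr_final = 0.01,
                       sigma0 = NULL, sigma_final = 0.5,
                       init = c("uniform", "gaussian", "sample"),
                       seed = 1L, shuffle = TRUE) {
  init <- match.arg(init)
  if (epochs < 0 || epochs != round(epochs)) {
    stop("epochs must be a nonnegative integer", call. = FALSE)
  }
  if (!(lr0 >= lr_final && lr_final > 0)) {
    stop("need lr0 >= lr_final > 0", call. = FALSE)
  }
  if (!is.null(sigma0) && !(sigma0 >= sigma_final)) {
    stop("need sigma0 >= sigma_final", call. = FALSE)
  }
  if (sigma_final <= 0) stop("need sigma_final > 0", call. = FALSE)
  structure(
    list(epochs = as.integer(epochs), lr0 = lr0, lr_final = lr_final,
         sigma0 = sigma0, sigma_final = sigma_final, init = init,
         seed = as.integer(seed), shuffle = isTRUE(shuffle)),
    class = "som_config"
  )
}

#' Initialize SOM weights
#'
#' Draws the initial `M x D` weight matrix under the scheme named in
#' `config$init`. With data supplied, `"uniform"` draws i.i.d. entries on
#' each dimension's observed `[min, max]`; `"gaussian"` draws from each
#' dimension's mean/sd; `"sample"` picks `M` distinct data rows without
#' replacement. Without data, `"uniform"` uses `[0, 1]` and `"gaussian"`
#' standard normals.
#'
#' @param n_neurons Number of neurons `M`.
#' @param d Weight dimension (must match the data).
#' @param config A [som_config()].
#' @param data Optional data matrix used to scale the draw.
#' @return A `som_model` object (untrained): list with `n_neurons`,
#'   `weights`, `metric` (`NA` until trained), `config`.
#' @export
init_som <- function(n_neurons, d, config = som_config(), data = NULL) {
  stopifnot(n_neurons >= 1, d >= 1)
  set.seed(config$seed)
  M <- as.integer(n_neurons)
  if (!is.null(data)) {
    data <- as.matrix(data)
    stopifnot(ncol(data) == d)
  }
  W <- switch(config$init,
    uniform = {
      if (is.null(data)) {
        matrix(runif(M * d), M, d)
      } else {
        lo <- apply(data, 2, min)
        hi <- apply(data, 2, max)
        t(replicate(M, runif(d, lo, hi), simplify = TRUE))
      }
    },
    gaussian = {
      if (is.null(data)) {
        matrix(rnorm(M * d), M, d)
      } else {
        mu <- colMeans(data)
        s <- apply(data, 2, sd)
        s[!is.finite(s) | s == 0] <- 1e-8
        t(replicate(M, rnorm(d, mu, s), simplify = TRUE))
      }
    },
    sample = {
      if (is.null(data)) stop("init = \"sample\" requires data", call. = FALSE)
      if (nrow(data) < M) {
        stop("init = \"sample\" needs at least M = ", M, " data rows",
             call. = FALSE)
      }
      data[sample.int(nrow(data), M), , drop = FALSE]
    }
  )
  W <- matrix(as.numeric(W), M, d)
  structure(
    list(n_neurons = M, weights = W, metric = NA_character_, config = config),
    class = "som_model"
  )
}

#' Train a 1-D Kohonen self-organizing map
#'
#' Online training: per presentation step, the best matching unit (BMU) under
#' `metric` is found and every neuron `m` is updated by
#' `w_m <- w_m + alpha(t) * h(m, b, t) * (f - w_m)` with the Gaussian chain
#' neighbourhood `h = exp(-(m - b)^2 / (2 sigma(t)^2))`. The metric affects
#' only the winner search; the update rule is additive for both metrics.
#' The inner loop is compiled; all randomness (initialization and per-epoch
#' shuffles) is drawn from R's RNG, so results are bit-reproducible given
#' `config$seed`.
#'
#' @param data Numeric `N x D` matrix (rows are samples).
#' @param n_neurons Number of output neurons = number of clusters.
#' @param metric `"cosine"` or `"euclidean"` winner matching.
#' @param config A [som_config()].
#' @return A `som_model`: list with `n_neurons`, `weights` (`M x D`),
#'   `metric`, `config`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 10), 30))
#' m <- train_som(x, 2, "euclidean", som_config(epochs = 20, seed = 1))
#' table(assign_clusters(x, m))
#' @export
train_som <- function(data, n_neurons, metric = c("cosine", "euclidean"),
                      config = som_config()) {
  metric <- match.arg(metric)
  data <- as.matrix(data)
  if (nrow(data) < 1) stop("need at least one data row", call. = FALSE)
  if (!all(is.finite(data))) stop("data must be finite", call. = FALSE)
  if (metric == "cosine" && any(sqrt(rowSums(data^2)) < .EPS)) {
    stop("cosine training is undefined for zero-norm data rows", call. = FALSE)
  }
  if (!inherits(config, "som_config")) stop("config must be a som_config",
                                            call. = FALSE)
  model <- init_som(n_neurons, ncol(data), config, data = data)
  M <- model$n_neurons
  sigma0 <- config$sigma0
  if (is.null(sigma0)) sigma0 <- max(M / 2, config$sigma_final)

  n <- nrow(data)
  if (config$epochs > 0) {
    order_mat <- t(vapply(seq_len(config$epochs), function(e) {
      if (config$shuffle) sample.int(n) else seq_len(n)
    }, integer(n)))
    order_mat <- matrix(as.integer(order_mat), nrow = config$epochs)
    model$weights <- som_train_cpp(data, model$weights, order_mat,
                                   metric == "cosine",
                                   config$lr0, config$lr_final,
                                   sigma0, config$sigma_final)
  }
  model$metric <- metric
  model
}

#' @export
print.som_model <- function(x, ...) {
  cat("1-D SOM: ", x$n_neurons, " neurons, D = ", ncol(x$weights),
      ", metric = ", x$metric, "\n", sep = "")
  invisible(x)
}

#' Best matching unit for one feature vector
#'
#' Returns the index of the neuron whose weight vector is closest to `f`
#' under the model's metric; ties break to the lowest index.
#'
#' @param f Numeric feature vector.
#' @param model A `som_model`.
#' @return Integer neuron index in `1..M`.
#' @export
find_bmu <- function(f, model) {
  stopifnot(inherits(model, "som_model"))
  metric <- if (is.na(model$metric)) "euclidean" else model$metric
  d <- .dist_rows(matrix(f, nrow = 1), model$weights, metric)
  which.min(d[1, ])
}

#' Assign every data row to its best matching unit
#'
#' @param data Numeric `N x D` matrix.
#' @param model A `som_model`.
#' @return Integer vector of neuron indices (length `N`).
#' @export
assign_clusters <- function(data, model) {
  stopifnot(inherits(model, "som_model"))
  data <- as.matrix(data)
  metric <- if (is.na(model$metric)) "euclidean" else model$metric
  d <- .dist_rows(data, model$weights, metric)
  max.col(-d, ties.method = "first")
}

#' Quantization error of a trained map
#'
#' Per sample, the squared distance to its best matching unit under the
#' model's metric; the reported value is the mean over all samples. Lower
#' values mean the prototypes tile the data more tightly; it is primarily a
#' training-progress diagnostic, and it mechanically favours larger maps.
#'
#' @param data Numeric `N x D` matrix.
#' @param model A `som_model`.
#' @return Mean squared point-to-BMU distance (nonnegative scalar).
#' @export
quantization_error <- function(data, model) {
  stopifnot(inherits(model, "som_model"))
  data <- as.matrix(data)
  if (nrow(data) == 0) stop("empty data", call. = FALSE)
  metric <- if (is.na(model$metric)) "euclidean" else model$metric
  d <- .dist_rows(data, model$weights, metric)
  mean(apply(d, 1, min)^2)
}

#' Serialize / restore a SOM model as JSON
#'
#' Full float precision; optionally stores the data-mean centroids of the
#' training assignment so a saved model can score unseen sequences with the
#' same reference centroids.
#'
#' @param model A `som_model`.
#' @param path JSON file path.
#' @param centroids Optional `M x D` matrix stored alongside the weights.
#' @return `write_som`: `path` invisibly. `read_som`: a `som_model` (with a
#'   `centroids` element when one was stored).
#' @export
write_som <- function(model, path, centroids = NULL) {
  stopifnot(inherits(model, "som_model"))
  obj <- list(n_neurons = model$n_neurons,
              metric = model$metric,
              weights = model$weights,
              config = Filter(Negate(is.null), unclass(model$config)))
  if (!is.null(centroids)) obj$centroids <- as.matrix(centroids)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_som
#' @export
read_som <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cfg <- do.call(som_config, obj$config[setdiff(names(obj$config), NULL)])
  model <- structure(
    list(n_neurons = as.integer(obj$n_neurons),
         weights = matrix(as.numeric(obj$weights), nrow = obj$n_neurons),
         metric = obj$metric,
         config = cfg),
    class = "som_model"
  )
  if (!is.null(obj$centroids)) {
    model$centroids <- matrix(as.numeric(obj$centroids),
                              nrow = obj$n_neurons)
  }
  model
}
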