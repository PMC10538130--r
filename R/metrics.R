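#' Cosine distance between two feature vectors
#'
#' Computes `1 - (x . y) / (||x|| ||y||)`, the dissimilarity used for winner
#' matching and discriminant scoring when the map is trained in cosine mode.
#' The value lies in `[0, 2]`: 0 for positively collinear vectors, 1 for
#' orthogonal vectors, 2 for antipodal vectors. It is invariant under positive
#' rescaling of either argument, which is why it groups postures by the
#' *direction* of the skeleton configuration (e.g. trunk inclination) rather
#' than by its magnitude.
#'
#' @param x,y Numeric vectors of equal length with nonzero norm.
#' @return A single number in `[0, 2]`.
#' @examples
#' cosine_distance(c(1, 0), c(0, 1)) # orthogonal -> 1
#' cosine_distance(c(1, 2, 3), c(2, 4, 6)) # collinear -> 0
#' @seealso [euclidean_distance()]
#' @export
cosine_distance <- function(x, y) {
  .check_pair(x, y)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx < .EPS || ny < .EPS) {
    stop("cosine distance is undefined for a zero-norm vector ",
         "(all-zero skeleton frame?)", call. = FALSE)
  }
  1 - sum(x * y) / (nx * ny)
}

#' Euclidean distance between two feature vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return `||x - y||`, a nonnegative number.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(x, y) {
  .check_pair(x, y)
  sqrt(sum((x - y)^2))
}

.check_pair <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("inputs must be numeric vectors", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("dimension mismatch: ", length(x), " vs ", length(y), call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

.match_metric <- function(metric) {
  match.arg(metric, c("cosine", "euclidean"))
}

# pointwise distance under a named metric
.dist_point <- function(x, y, metric) {
  if (metric == "cosine") cosine_distance(x, y) else euclidean_distance(x, y)
}

# N x M matrix of distances from rows of X to rows of C, vectorized.
# Under cosine, any zero-norm row of X or C is an error.
.dist_rows <- function(X, C, metric) {
  X <- as.matrix(X)
  C <- as.matrix(C)
  if (ncol(X) != ncol(C)) {
    stop("dimension mismatch: data D=", ncol(X), ", centers D=", ncol(C),
         call. = FALSE)
  }
  if (metric == "cosine") {
    nx <- sqrt(rowSums(X^2))
    nc <- sqrt(rowSums(C^2))
    if (any(nx < .EPS)) {
      stop("cosine distance is undefined for zero-norm data row(s): ",
           paste(which(nx < .EPS)[1:min(3, sum(nx < .EPS))], collapse = ", "),
           call. = FALSE)
    }
    if (any(nc < .EPS)) {
      stop("cosine distance is undefined for zero-norm center(s)",
           call. = FALSE)
    }
    D <- 1 - (X %*% t(C)) / outer(nx, nc)
    # clamp tiny negative round-off
    D[D < 0 & D > -1e-12] <- 0
    D
  } else {
    # exact per-center differences (the dot-product expansion loses ~1e-8
    # relative precision, which the index oracles would see)
    D <- matrix(0, nrow(X), nrow(C))
    for (m in seq_len(nrow(C))) {
      diff <- X - matrix(C[m, ], nrow(X), ncol(X), byrow = TRUE)
      D[, m] <- sqrt(rowSums(diff^2))
    }
    D
  }
}
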