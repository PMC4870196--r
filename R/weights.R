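# k-nearest-neighbour spatial weights and Moran's I diagnostics.

#' Row-standardized k-nearest-neighbour spatial weights
#'
#' Each cell is linked to its `k` nearest neighbours by Euclidean centroid
#' distance, each with weight `1/k`; the resulting weight matrix is
#' generally asymmetric. Distance ties are broken by cell index order.
#' The eigenvalues needed by the SAR log-determinant are computed lazily on
#' first use and cached inside the object.
#'
#' @param coords n x 2 matrix or data frame of centroid coordinates (km).
#' @param k number of neighbours, `1 <= k < n`.
#' @return object of class `spatial_weights`: list with dense matrix `W`,
#'   neighbour index matrix `neighbors` (n x k), `k`, `n`, `coords`.
#' @export
knn_weights <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1 || k >= n) stop_("k must satisfy 1 <= k < n")
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  nb <- t(apply(d, 1L, function(x) order(x)[seq_len(k)]))
  if (k == 1L) nb <- matrix(nb, ncol = 1L)
  W <- matrix(0, n, n)
  W[cbind(rep(seq_len(n), each = k), as.vector(t(nb)))] <- 1 / k
  structure(list(W = W, neighbors = nb, k = as.integer(k), n = n,
                 coords = coords, cache = new.env(parent = emptyenv())),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("kNN spatial weights: n = %d, k = %d, row-standardized\n",
              x$n, x$k))
  invisible(x)
}

# memoized (complex) spectrum of W, used by the SAR log-determinant
.sw_eigenvalues <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (is.null(w$cache$ev))
    w$cache$ev <- eigen(w$W, only.values = TRUE)$values
  w$cache$ev
}

#' Moran's I spatial autocorrelation test
#'
#' `I = (n / S0) * (z' W z) / (z' z)` for centered values `z`, with the
#' expectation `-1/(n-1)`, the variance under the normality assumption, and
#' a two-sided normal-approximation p-value.
#'
#' @param values numeric vector (length n >= 4); centered internally.
#' @param weights a [knn_weights()] object or plain n x n weight matrix.
#' @return list with `statistic`, `expectation`, `variance`, `p.value`
#'   (all `NA` for constant input).
#' @export
morans_i <- function(values, weights) {
  W <- if (inherits(weights, "spatial_weights")) weights$W else
    as.matrix(weights)
  n <- length(values)
  stopifnot(nrow(W) == n, ncol(W) == n)
  if (n < 4L) stop_("need at least 4 observations")
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0)
    return(list(statistic = NA_real_, expectation = NA_real_,
                variance = NA_real_, p.value = NA_real_))
  S0 <- sum(W)
  I <- (n / S0) * drop(crossprod(z, W %*% z)) / denom
  E <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  # variance under the normality assumption
  V <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - E^2
  p <- 2 * pnorm(-abs((I - E) / sqrt(V)))
  list(statistic = I, expectation = E, variance = V, p.value = p)
}
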