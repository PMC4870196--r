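#' Simulate a response with SAR-error spatial structure
#'
#' Draws `y = X beta + u` with simultaneous-autoregressive errors
#' `u = lambda W u + eps`, i.e. `u = (I - lambda W)^-1 eps`,
#' `eps ~ iid N(0, sigma^2)`. This is the generative counterpart of the
#' spatial-error regression fitted by [fit_sar_error()] and is used for
#' parameter-recovery experiments.
#'
#' @param X design matrix (n x p); pass a column of ones yourself if the
#'   simulated truth includes an intercept.
#' @param W spatial weights: a [knn_weights()] object or a plain n x n
#'   matrix (row-standardized weights are assumed, so `|lambda| < 1`
#'   guarantees invertibility in the generic case).
#' @param beta coefficient vector of length `ncol(X)`.
#' @param lambda spatial-error parameter, `|lambda| < 1`.
#' @param sigma innovation standard deviation.
#' @param seed optional integer seed (deterministic output when fixed).
#' @return numeric response vector of length n.
#' @export
simulate_sar_response <- function(X, W, beta, lambda, sigma, seed = NULL) {
  X <- as.matrix(X)
  Wm <- if (inherits(W, "spatial_weights")) W$W else as.matrix(W)
  n <- nrow(X)
  stopifnot(nrow(Wm) == n, ncol(Wm) == n, length(beta) == ncol(X),
            is.numeric(sigma), sigma >= 0)
  if (abs(lambda) >= 1)
    stop_("|lambda| must be < 1 for row-standardized weights")
  A <- diag(n) - lambda * Wm
  if (rcond(A) < 1e-12)
    stop_("I - lambda*W is computationally singular")
  eps <- local_seed(seed, rnorm(n, 0, sigma))
  u <- solve(A, eps)
  drop(X %*% beta) + u
}
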