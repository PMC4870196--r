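# Collinearity-constrained candidate enumeration, AIC model averaging,
# and the residual-autocorrelation-driven choice of k.

#' Group predictors by pairwise collinearity
#'
#' Builds a graph with an edge between every pair of predictors whose
#' absolute Pearson correlation exceeds `threshold` and returns its
#' connected components of size >= 2 (so grouping is transitive: A-B and
#' B-C collinear places A, B, C in one group even if A-C is not).
#' Predictors in no group are unconstrained singletons.
#'
#' @param X data frame or matrix of numeric predictors (>= 2 columns).
#' @param threshold absolute-correlation threshold (default 0.5, strict
#'   inequality).
#' @return list of character vectors (the groups); attribute `"singletons"`
#'   holds the free predictors.
#' @export
collinearity_groups <- function(X, threshold = 0.5) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop_("need at least two predictors")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop_("constant predictor column(s): ",
          paste(colnames(X)[sds == 0], collapse = ", "))
  adj <- abs(cor(X)) > threshold
  diag(adj) <- FALSE
  p <- ncol(X)
  comp <- rep(NA_integer_, p)
  cid <- 0L
  for (s in seq_len(p)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  nm <- colnames(X)
  groups <- split(nm, comp)
  sizes <- lengths(groups)
  out <- unname(groups[sizes >= 2L])
  attr(out, "singletons") <- unlist(unname(groups[sizes == 1L]))
  out
}

#' Enumerate candidate model formulas under group constraints
#'
#' Full models take exactly one predictor from each collinearity group plus
#' every free predictor; the candidate set is every distinct non-empty
#' subset of any full model. Duplicated subsets arising from overlapping
#' full-model lattices are enumerated (and later fitted) only once. The
#' ordering is deterministic: by model size, then alphabetically.
#'
#' @param predictors character vector of all predictor names.
#' @param groups list of character vectors (disjoint subsets of
#'   `predictors`), e.g. from [collinearity_groups()].
#' @return list of character vectors (one per candidate model); attributes
#'   `"full_models"` (list) and `"n_full"`.
#' @export
enumerate_candidates <- function(predictors, groups = list()) {
  predictors <- as.character(predictors)
  if (anyDuplicated(predictors)) stop_("duplicated predictor names")
  gvars <- unlist(groups)
  if (anyDuplicated(gvars)) stop_("collinearity groups must be disjoint")
  if (!all(gvars %in% predictors))
    stop_("group members must be predictors")
  free <- setdiff(predictors, gvars)
  if (length(groups)) {
    pick <- expand.grid(lapply(groups, identity),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    fulls <- lapply(seq_len(nrow(pick)),
                    function(i) c(unlist(pick[i, ], use.names = FALSE), free))
  } else {
    fulls <- list(free)
  }
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (fm in fulls) {
    fm <- fm[order(match(fm, predictors))]
    m <- length(fm)
    for (code in seq_len(2^m - 1L)) {
      sub <- fm[bitwAnd(code, 2^(seq_len(m) - 1L)) > 0]
      key <- paste(sort(sub), collapse = "|")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- sub
      }
    }
  }
  keys <- vapply(out, function(v) paste(sort(v), collapse = "|"), "")
  ord <- order(lengths(out), keys)
  out <- out[ord]
  attr(out, "full_models") <- fulls
  attr(out, "n_full") <- length(fulls)
  out
}

#' Akaike-weight model averaging of SAR fits
#'
#' Retains every fitted model whose AIC lies within `delta_max` of the best
#' model, computes Akaike weights `w_i = exp(-Delta_i/2) / sum_j
#' exp(-Delta_j/2)` over the retained set, and reports for each predictor
#' the weighted mean standardized coefficient and its importance (the sum
#' of weights of retained models containing it). By default a predictor
#' absent from a model contributes a zero coefficient to the average
#' (zero substitution), so coefficients and importances share one weight
#' base; `conditional = TRUE` averages only over the models that contain
#' the predictor.
#'
#' @param fits list of [fit_sar_error()] results (>= 1).
#' @param delta_max AIC window; the best model is always retained.
#' @param conditional use conditional averaging instead of zero
#'   substitution.
#' @return object of class `sar_average`: `table` (predictor, coefficient,
#'   importance), `models` (model, aic, delta, weight, retained flag),
#'   `best` (index of the lowest-AIC fit), `delta_max`, `conditional`.
#' @export
model_average <- function(fits, delta_max = 10, conditional = FALSE) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "sar_fit")))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  delta <- aic - min(aic)
  keep <- delta < delta_max
  w <- exp(-delta[keep] / 2)
  w <- w / sum(w)
  preds <- unique(unlist(lapply(fits, `[[`, "predictors")))
  kept <- fits[keep]
  coef_mat <- vapply(kept, function(f) {
    b <- setNames(rep(0, length(preds)), preds)
    b[f$predictors] <- f$coefficients[f$predictors]
    b
  }, numeric(length(preds)))
  coef_mat <- matrix(coef_mat, nrow = length(preds),
                     dimnames = list(preds, NULL))
  present <- vapply(kept, function(f) preds %in% f$predictors,
                    logical(length(preds)))
  present <- matrix(present, nrow = length(preds))
  importance <- as.numeric(present %*% w)
  coefficient <- if (conditional) {
    vapply(seq_along(preds), function(i) {
      wi <- w[present[i, ]]
      if (!length(wi)) return(NA_real_)
      sum(coef_mat[i, present[i, ]] * wi) / sum(wi)
    }, numeric(1))
  } else {
    as.numeric(coef_mat %*% w)
  }
  model_key <- vapply(fits, function(f)
    paste(f$predictors, collapse = " + "), "")
  weight_all <- rep(NA_real_, length(fits))
  weight_all[keep] <- w
  structure(list(
    table = data.frame(predictor = preds, coefficient = coefficient,
                       importance = importance, stringsAsFactors = FALSE),
    models = data.frame(model = model_key, aic = aic, delta = delta,
                        weight = weight_all, retained = keep,
                        stringsAsFactors = FALSE),
    best = which.min(aic), delta_max = delta_max,
    conditional = conditional), class = "sar_average")
}

#' @export
print.sar_average <- function(x, ...) {
  cat(sprintf("Akaike model averaging: %d of %d models retained (dAIC < %g)\n",
              sum(x$models$retained), nrow(x$models), x$delta_max))
  tab <- x$table[order(-x$table$importance), ]
  print(data.frame(predictor = tab$predictor,
                   coefficient = round(tab$coefficient, 4),
                   importance = round(tab$importance, 3),
                   row.names = NULL))
  invisible(x)
}

#' Choose k for the spatial weights by residual Moran's I
#'
#' Fits the full SAR-error model with k-nearest-neighbour weights for
#' `k = k_start, k_start - 1, ..., k_min` and returns the first k whose
#' spatially filtered residuals show no significant Moran autocorrelation
#' at level `alpha`. If no k passes, the result carries `k = k_min` with
#' `whitened = FALSE` and a warning.
#'
#' @param y response vector.
#' @param X full predictor matrix or data frame.
#' @param coords n x 2 centroid coordinates.
#' @param k_start,k_min inclusive search range, decreasing (defaults 10, 4).
#' @param alpha significance level for the residual Moran test.
#' @param ... passed to [fit_sar_error()].
#' @return list with `k`, `fit`, `weights`, `moran` (the accepted test),
#'   `whitened` (logical) and `trace` (per-k Moran statistic and p-value).
#' @export
select_k <- function(y, X, coords, k_start = 10, k_min = 4, alpha = 0.05,
                     ...) {
  stopifnot(k_start >= k_min, k_min >= 1)
  if (length(y) <= k_start) stop_("need n > k_start observations")
  trace <- data.frame(k = integer(0), moran_i = numeric(0),
                      p.value = numeric(0))
  last <- NULL
  for (k in seq(k_start, k_min)) {
    w <- knn_weights(coords, k)
    fit <- fit_sar_error(y, X, w, ...)
    mt <- morans_i(fit$residuals_filtered, w)
    trace <- rbind(trace, data.frame(k = k, moran_i = mt$statistic,
                                     p.value = mt$p.value))
    last <- list(k = k, fit = fit, weights = w, moran = mt,
                 whitened = !is.na(mt$p.value) && mt$p.value >= alpha,
                 trace = trace)
    if (last$whitened) return(last)
  }
  warning("residual spatial autocorrelation remained significant down to ",
          "k = ", k_min, "; returning k = ", k_min)
  last$trace <- trace
  last
}
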