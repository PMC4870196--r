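# Per-cell environmental predictors: water balance, elevation
# heterogeneity, temperature-change velocity, climate-space PCA, and
# least-cost postglacial accessibility.

#' Annual water balance
#'
#' `WBL = MAP - PET` (mm): annual precipitation minus annually summed
#' potential evapotranspiration; negative in arid cells.
#'
#' @param map annual precipitation per cell, mm.
#' @param pet annual potential evapotranspiration per cell, mm.
#' @return numeric vector, mm.
#' @export
water_balance <- function(map, pet) {
  if (!all(is.finite(map)) || !all(is.finite(pet)))
    stop_("water balance inputs must be finite")
  if (length(map) != length(pet)) stop_("MAP and PET lengths differ")
  map - pet
}

#' Elevation heterogeneity per cell
#'
#' Standard deviation of the sub-cell elevation samples of each grid cell
#' (m). Cells with fewer than two non-missing samples are `NA`. The
#' downstream predictor table stores `sqrt(EHET)`.
#'
#' @param elev cells x samples matrix of sub-cell elevations (m).
#' @param denom `"n-1"` (default, sample sd) or `"n"` (population sd).
#' @return numeric vector of per-cell standard deviations, m.
#' @export
elevation_heterogeneity <- function(elev, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  elev <- as.matrix(elev)
  apply(elev, 1L, function(x) {
    x <- x[!is.na(x)]
    k <- length(x)
    if (k < 2L) return(NA_real_)
    s <- sd(x)
    if (denom == "n") s * sqrt((k - 1) / k) else s
  })
}

# gradient magnitude of a gridded field, central differences in the
# interior and one-sided differences on the boundary; h = cell size (km)
.gradient_magnitude <- function(m, h) {
  R <- nrow(m); C <- ncol(m)
  gx <- matrix(0, R, C)
  gy <- matrix(0, R, C)
  if (C >= 3) gx[, 2:(C - 1)] <- (m[, 3:C] - m[, 1:(C - 2)]) / (2 * h)
  if (C >= 2) {
    gx[, 1] <- (m[, 2] - m[, 1]) / h
    gx[, C] <- (m[, C] - m[, C - 1]) / h
  }
  if (R >= 3) gy[2:(R - 1), ] <- (m[3:R, ] - m[1:(R - 2), ]) / (2 * h)
  if (R >= 2) {
    gy[1, ] <- (m[2, ] - m[1, ]) / h
    gy[R, ] <- (m[R, ] - m[R - 1, ]) / h
  }
  sqrt(gx^2 + gy^2)
}

#' Temperature-change velocity since the LGM
#'
#' Velocity of temperature change: the temporal rate of MAT change between
#' the Last Glacial Maximum and the present divided by the local spatial MAT
#' gradient, in km/yr - the displacement rate of a temperature isocline,
#' i.e. how fast a population must migrate to keep its temperature. The
#' spatial gradient is the magnitude of the central-difference gradient of
#' the current MAT field (one-sided on the boundary), floored at
#' `gradient_floor` so flat terrain yields a large finite velocity instead
#' of a division by zero.
#'
#' @param mat_now,mat_lgm current and LGM mean annual temperature as
#'   row x column matrices (see [layer_matrix()]), degC.
#' @param cell_size cell edge length, km.
#' @param elapsed time since the LGM, yr (default 21,000).
#' @param gradient_floor minimum spatial gradient, degC/km.
#' @return matrix of velocities, km/yr.
#' @export
temperature_velocity <- function(mat_now, mat_lgm, cell_size,
                                 elapsed = 21000, gradient_floor = 1e-4) {
  mat_now <- as.matrix(mat_now); mat_lgm <- as.matrix(mat_lgm)
  if (!identical(dim(mat_now), dim(mat_lgm)))
    stop_("current and LGM temperature grids are not aligned")
  if (elapsed <= 0) stop_("elapsed time must be positive")
  grad <- .gradient_magnitude(mat_now, cell_size)
  (abs(mat_now - mat_lgm) / elapsed) / pmax(grad, gradient_floor)
}

#' Principal components of the climate space
#'
#' Standardizes the bioclim-like layers to zero mean and unit variance
#' (i.e. a correlation-matrix PCA, appropriate for variables of mixed
#' units) and returns the scores on the leading components, ordered by
#' explained variance. Signs are fixed so that each component's
#' largest-magnitude loading is positive, making the decomposition
#' reproducible. Rank-deficient inputs yield fewer components with a
#' warning.
#'
#' @param bioclim cells x layers numeric matrix (>= `n_components` layers).
#' @param n_components number of leading components requested (default 3).
#' @param tol relative singular-value tolerance below which a component is
#'   treated as null.
#' @return list with `scores` (cells x k), `loadings` (layers x k),
#'   `sdev` and `prop_var` (per retained component).
#' @export
climate_pca <- function(bioclim, n_components = 3, tol = 1e-8) {
  B <- as.matrix(bioclim)
  if (ncol(B) < n_components)
    stop_("need at least ", n_components, " input layers")
  sds <- apply(B, 2L, sd)
  if (any(sds == 0))
    stop_("constant layer(s): ", paste(colnames(B)[sds == 0], collapse = ", "))
  Bs <- scale(B)
  pr <- prcomp(Bs, center = FALSE, scale. = FALSE)
  keep <- which(pr$sdev > tol * pr$sdev[1L])
  k <- min(n_components, length(keep))
  if (k < n_components)
    warning("rank-deficient climate space: returning ", k,
            " of ", n_components, " requested components")
  scores <- pr$x[, seq_len(k), drop = FALSE]
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = load,
       sdev = pr$sdev[seq_len(k)],
       prop_var = pr$sdev[seq_len(k)]^2 / sum(pr$sdev^2))
}

#' Cost graph between neighbouring grid cells in climate space
#'
#' Connects every cell to its 8 (queen, default) or 4 (rook) grid
#' neighbours with an edge weighted by the Euclidean distance between the
#' two cells' climate-PCA scores. No geometric diagonal correction is
#' applied: the costs are purely climatic.
#'
#' @param scores cells x components score matrix from [climate_pca()].
#' @param cells cell table with `row`, `col` and `cell_id` columns.
#' @param connectivity 8 (queen) or 4 (rook).
#' @return object of class `cost_graph`: list with `edges`
#'   (`from`, `to`, `weight`), `n`, `cell_id`, `connectivity`.
#' @export
climate_cost_graph <- function(scores, cells, connectivity = 8) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == nrow(cells),
            all(c("row", "col", "cell_id") %in% names(cells)))
  if (!connectivity %in% c(4, 8)) stop_("connectivity must be 4 or 8")
  R <- max(cells$row); C <- max(cells$col)
  idx <- matrix(NA_integer_, R, C)
  idx[cbind(cells$row, cells$col)] <- seq_len(nrow(cells))
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- cells$row + o[1L]; c2 <- cells$col + o[2L]
    ok <- r2 >= 1L & r2 <= R & c2 >= 1L & c2 <= C
    j <- idx[cbind(r2[ok], c2[ok])]
    keep <- !is.na(j)
    from <- c(from, which(ok)[keep])
    to <- c(to, j[keep])
  }
  w <- sqrt(rowSums((scores[from, , drop = FALSE] -
                     scores[to, , drop = FALSE])^2))
  structure(list(edges = data.frame(from = from, to = to, weight = w),
                 n = nrow(cells), cell_id = as.character(cells$cell_id),
                 connectivity = connectivity),
            class = "cost_graph")
}

#' Postglacial accessibility from least-cost distances
#'
#' Multi-source shortest paths (Dijkstra) from every LGM forest source cell
#' through the climate-space cost graph give each cell its accumulated cost
#' `D` to the nearest source; accessibility is `ACC = 1 / (D + 1)`, so
#' `ACC = 1` exactly on source cells (in-situ glacial forest) and `ACC = 0`
#' for cells unreachable from any source.
#'
#' @param graph a `cost_graph` from [climate_cost_graph()].
#' @param sources logical mask over cells, integer cell indices, or cell
#'   ids; at least one source is required.
#' @return data frame with `cell_id`, `cost` (accumulated least cost; `Inf`
#'   when unreachable) and `acc`.
#' @export
least_cost_accessibility <- function(graph, sources) {
  stopifnot(inherits(graph, "cost_graph"))
  if (is.logical(sources)) {
    stopifnot(length(sources) == graph$n)
    src <- which(sources)
  } else if (is.character(sources)) {
    src <- match(sources, graph$cell_id)
    if (anyNA(src)) stop_("unknown source cell id(s)")
  } else {
    src <- as.integer(sources)
    stopifnot(all(src >= 1L), all(src <= graph$n))
  }
  if (length(src) == 0L)
    stop_("at least one LGM forest source cell is required")
  if (any(graph$edges$weight < 0)) stop_("edge costs must be non-negative")
  g <- igraph::make_graph(rbind(graph$edges$from, graph$edges$to),
                          n = graph$n, directed = FALSE)
  dmat <- igraph::distances(g, v = src, weights = graph$edges$weight,
                            algorithm = "dijkstra")
  dmin <- apply(dmat, 2L, min)
  data.frame(cell_id = graph$cell_id,
             cost = dmin,
             acc = ifelse(is.finite(dmin), 1 / (1 + dmin), 0),
             stringsAsFactors = FALSE)
}

# natural log with a configurable positive offset substituted for zeros
.log_with_offset <- function(x, offset = NULL) {
  if (any(x < 0)) stop_("negative values cannot be log-transformed here")
  if (is.null(offset)) {
    pos <- x[x > 0]
    offset <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  }
  if (offset <= 0) stop_("the log offset must be positive")
  list(value = log(ifelse(x > 0, x, offset)), offset = offset)
}

#' Assemble the transformed predictor table
#'
#' Joins the eight modelling predictors per cell and applies the variance-
#' stabilizing transforms used throughout the analysis: natural log for
#' accessibility (ACC) and velocity (VT) - zeros replaced by a configurable
#' positive offset recorded in the output metadata - and square root for
#' elevation heterogeneity (EHET); MAT, TMIN, TES, WBL and PRS pass through
#' untransformed.
#'
#' @param stack a `climate_stack` (supplies MAT, TMIN, TES, MAP, PET, PRS).
#' @param acc per-cell accessibility in `[0, 1]` (e.g.
#'   `least_cost_accessibility(...)$acc`).
#' @param vt per-cell temperature velocity, km/yr (vector in cell order;
#'   use [layer_matrix()]/`t()` helpers or [run_all()] which handles it).
#' @param ehet per-cell elevation heterogeneity, m.
#' @param offset_acc,offset_vt optional positive offsets substituted for
#'   zero ACC / VT before the log; default half the smallest positive value.
#' @return data frame (`cell_id`, `MAT`, `TMIN`, `TES`, `WBL`, `PRS`,
#'   `EHET`, `VT`, `ACC`) with attribute `"transforms"` documenting each
#'   applied transform and offset.
#' @export
build_predictor_table <- function(stack, acc, vt, ehet,
                                  offset_acc = NULL, offset_vt = NULL) {
  stopifnot(inherits(stack, "climate_stack"))
  n <- nrow(stack$cells)
  acc <- as.numeric(acc); vt <- as.numeric(vt); ehet <- as.numeric(ehet)
  stopifnot(length(acc) == n, length(vt) == n, length(ehet) == n)
  if (any(ehet < 0, na.rm = TRUE))
    stop_("elevation heterogeneity cannot be negative")
  la <- .log_with_offset(acc, offset_acc)
  lv <- .log_with_offset(vt, offset_vt)
  tab <- data.frame(cell_id = stack$cells$cell_id,
                    MAT = stack$current$MAT,
                    TMIN = stack$current$TMIN,
                    TES = stack$current$TES,
                    WBL = water_balance(stack$current$MAP, stack$current$PET),
                    PRS = stack$current$PRS,
                    EHET = sqrt(ehet),
                    VT = lv$value,
                    ACC = la$value,
                    stringsAsFactors = FALSE)
  attr(tab, "transforms") <- list(
    ACC = list(transform = "log", zero_offset = la$offset),
    VT = list(transform = "log", zero_offset = lv$offset),
    EHET = list(transform = "sqrt"),
    MAT = "identity", TMIN = "identity", TES = "identity",
    WBL = "identity", PRS = "identity")
  tab
}
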