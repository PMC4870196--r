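#' Simulate gridded climate surfaces with an LGM counterpart
#'
#' Generates the per-cell environmental layers the analysis consumes:
#' current mean annual temperature (MAT), minimum temperature of the coldest
#' month (TMIN), temperature seasonality (TES), annual precipitation (MAP),
#' potential evapotranspiration (PET) and precipitation seasonality (PRS);
#' Last Glacial Maximum counterparts (MAT cooled by `lgm_offset` plus a
#' smooth low-frequency anomaly surface); 19 correlated bioclim-like layers
#' for the climate-space principal component analysis; and a sub-cell
#' elevation field with spatially varying roughness from which elevation
#' heterogeneity is later computed.
#'
#' MAT decreases with the row index at `gradient_strength` degC per row in
#' expectation (rows play the role of latitude bands); with `noise_sd = 0`
#' the dependence is exactly linear. All output is deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()] object; the grid must be at least 3x3.
#' @return an object of class `climate_stack`: a list with elements
#'   `cells` (cell_id, row, col, x_km, y_km), `current` and `lgm`
#'   (per-cell layer data frames), `bioclim` (cells x 19 matrix), `elev`
#'   (cells x `n_subcell` matrix, m), and the grid geometry.
#' @export
simulate_climate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  R <- config$grid_rows
  C <- config$grid_cols
  if (R < 3 || C < 3) stop_("the grid must be at least 3 x 3 cells")
  local_seed(child_seed(config$seed, 2L), {
    rr <- rep(seq_len(R), each = C)
    cc <- rep(seq_len(C), times = R)
    n <- R * C
    cells <- data.frame(
      cell_id = sprintf("c%04d", seq_len(n)),
      row = rr, col = cc,
      x_km = (cc - 0.5) * config$cell_size,
      y_km = (rr - 0.5) * config$cell_size,
      stringsAsFactors = FALSE)

    ns <- config$noise_sd
    colf <- if (C > 1) (cc - 1) / (C - 1) else rep(0, n)
    mat <- 25 - config$gradient_strength * (rr - 1) + rnorm(n, 0, ns)
    tmin <- mat - 12 - 0.15 * (rr - 1) + rnorm(n, 0, 0.5 * ns)
    tes <- 4 + 0.35 * (rr - 1) + rnorm(n, 0, 0.5 * ns)
    map <- 600 + 900 * colf + rnorm(n, 0, 50 * ns)
    pet <- pmax(0, 380 + 42 * (25 - config$gradient_strength * (rr - 1))) +
      rnorm(n, 0, 30 * ns)
    prs <- 25 + 30 * colf + rnorm(n, 0, 2 * ns)
    current <- data.frame(MAT = mat, TMIN = tmin, TES = tes,
                          MAP = map, PET = pet, PRS = prs)

    # smooth low-frequency LGM anomaly so velocity varies in space
    ph <- runif(2L, 0, 2 * pi)
    anom <- config$anomaly_amp *
      sin(2 * pi * 1.5 * (rr - 1) / max(R - 1, 1) + ph[1L]) *
      cos(2 * pi * 1.5 * (cc - 1) / max(C - 1, 1) + ph[2L])
    mat_lgm <- mat - config$lgm_offset + anom
    lgm <- data.frame(MAT_lgm = mat_lgm,
                      TES_lgm = tes + 1 + 0.3 * anom,
                      MAP_lgm = pmax(0, map - 150 + 25 * anom),
                      PRS_lgm = prs + 2,
                      PET_lgm = pmax(0, 380 + 42 * mat_lgm))

    # 19 bioclim-like layers: random mixtures of the four base gradients
    base <- cbind(scale_safe(mat), scale_safe(map),
                  scale_safe(tes), scale_safe(prs))
    A <- matrix(runif(19L * 4L, -1, 1), nrow = 19L)
    bioclim <- base %*% t(A) + matrix(rnorm(n * 19L, 0, 0.3), nrow = n)
    colnames(bioclim) <- sprintf("bio%02d", 1:19)

    # sub-cell elevation: base ramp + two-octave roughness, rougher eastward
    s <- max(2L, ceiling(sqrt(config$n_subcell)))
    nsub <- config$n_subcell
    base_elev <- 150 + 1100 * colf
    rough <- config$elev_roughness * (0.15 + 0.85 * colf)
    elev <- matrix(NA_real_, nrow = n, ncol = nsub)
    blk <- ceiling(s / 3)
    for (i in seq_len(n)) {
      low <- kronecker(matrix(rnorm(9L), 3L, 3L),
                       matrix(1, blk, blk))[seq_len(s), seq_len(s)]
      high <- matrix(rnorm(s * s), s, s)
      field <- 0.8 * low + 0.45 * high
      elev[i, ] <- base_elev[i] + rough[i] * as.vector(field)[seq_len(nsub)]
    }

    structure(list(cells = cells, current = current, lgm = lgm,
                   bioclim = bioclim, elev = elev,
                   grid_rows = R, grid_cols = C,
                   cell_size = config$cell_size),
              class = "climate_stack")
  })
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("Climate stack: %d x %d grid (%g km cells), %d cells\n",
              x$grid_rows, x$grid_cols, x$cell_size, nrow(x$cells)))
  cat(sprintf("  current layers: %s\n", paste(names(x$current), collapse = ", ")))
  cat(sprintf("  LGM layers    : %s\n", paste(names(x$lgm), collapse = ", ")))
  cat(sprintf("  bioclim-like  : %d layers; elevation: %d sub-cell samples\n",
              ncol(x$bioclim), ncol(x$elev)))
  invisible(x)
}

#' Reshape a per-cell layer into its row x column matrix
#'
#' Cells are stored in row-major order; several operations (the temperature
#' velocity gradient in particular) work on the rectangular field.
#'
#' @param stack a `climate_stack`.
#' @param layer layer name, looked up in `current` then `lgm`.
#' @return a `grid_rows` x `grid_cols` numeric matrix.
#' @export
layer_matrix <- function(stack, layer) {
  stopifnot(inherits(stack, "climate_stack"))
  v <- stack$current[[layer]] %||% stack$lgm[[layer]]
  if (is.null(v)) stop_("unknown layer: ", layer)
  matrix(v, nrow = stack$grid_rows, ncol = stack$grid_cols, byrow = TRUE)
}

# inverse of layer_matrix: rectangular field back to row-major cell order
cell_vector <- function(m) as.vector(t(m))

#' Binary LGM forest source mask from a climate envelope
#'
#' Marks as glacial forest refugia the cells whose LGM climate falls inside a
#' stated envelope. This is the pluggable stand-in for a hindcasted glacial
#' forest distribution: any externally supplied binary mask can be used in
#' its place by downstream functions.
#'
#' @param climate a `climate_stack`.
#' @param rule named list of `c(lower, upper)` bounds, one entry per layer
#'   (layers are looked up in the LGM table first, then the current one);
#'   all conditions are combined with AND. Bounds must be finite or infinite
#'   end-points, e.g. `list(MAT_lgm = c(5, Inf))`.
#' @return logical vector, one entry per cell, with at least one `TRUE`.
#' @export
make_lgm_forest_mask <- function(climate, rule) {
  stopifnot(inherits(climate, "climate_stack"))
  if (!is.list(rule) || is.null(names(rule)) || any(names(rule) == ""))
    stop_("'rule' must be a named list of c(lower, upper) bounds")
  mask <- rep(TRUE, nrow(climate$cells))
  for (nm in names(rule)) {
    b <- rule[[nm]]
    if (length(b) != 2L || any(is.na(b)))
      stop_("bounds for '", nm, "' must be c(lower, upper)")
    v <- climate$lgm[[nm]] %||% climate$current[[nm]]
    if (is.null(v)) stop_("unknown layer in envelope rule: ", nm)
    mask <- mask & v >= b[1L] & v <= b[2L]
  }
  if (!any(mask))
    stop_("the envelope rule selects no LGM forest source cells; ",
          "postglacial accessibility is undefined without at least one source")
  mask
}
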