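# Plain-text interchange: newick trees, assemblage/cell CSV, long-format
# climate CSV, and the pipeline output bundle.

#' Write and read a grid assemblage as CSV
#'
#' The presence/absence matrix is written with `cell_id` as the first
#' column followed by one 0/1 column per species; the cell table carries
#' centroids (km) and region labels.
#'
#' @param grid a `grid_assemblage`.
#' @param file_pa,file_cells output/input CSV paths.
#' @return `write_assemblage()` returns the paths invisibly;
#'   `read_assemblage()` returns a `grid_assemblage`.
#' @export
write_assemblage <- function(grid, file_pa, file_cells) {
  stopifnot(inherits(grid, "grid_assemblage"))
  pa <- data.frame(cell_id = rownames(grid$pa), grid$pa,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(pa, file_pa, row.names = FALSE)
  write.csv(grid$cells, file_cells, row.names = FALSE)
  invisible(c(file_pa, file_cells))
}

#' @rdname write_assemblage
#' @export
read_assemblage <- function(file_pa, file_cells) {
  pa <- read.csv(file_pa, check.names = FALSE, stringsAsFactors = FALSE)
  cells <- read.csv(file_cells, stringsAsFactors = FALSE)
  m <- as.matrix(pa[, -1L, drop = FALSE])
  rownames(m) <- pa$cell_id
  grid_assemblage(m, cells)
}

#' Write climate layers as a long-format CSV
#'
#' One row per cell x variable x period (`current`, `lgm`, `bioclim`).
#' Sub-cell elevation samples are written separately in wide format by
#' [write_elevation()].
#'
#' @param stack a `climate_stack`.
#' @param file output CSV path.
#' @return the path, invisibly.
#' @export
write_climate <- function(stack, file) {
  stopifnot(inherits(stack, "climate_stack"))
  blocks <- list(
    data.frame(cell_id = rep(stack$cells$cell_id, ncol(stack$current)),
               variable = rep(names(stack$current),
                              each = nrow(stack$cells)),
               period = "current",
               value = unlist(stack$current, use.names = FALSE)),
    data.frame(cell_id = rep(stack$cells$cell_id, ncol(stack$lgm)),
               variable = rep(names(stack$lgm), each = nrow(stack$cells)),
               period = "lgm",
               value = unlist(stack$lgm, use.names = FALSE)),
    data.frame(cell_id = rep(stack$cells$cell_id, ncol(stack$bioclim)),
               variable = rep(colnames(stack$bioclim),
                              each = nrow(stack$cells)),
               period = "bioclim",
               value = as.vector(stack$bioclim)))
  write.csv(do.call(rbind, blocks), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_climate
#' @export
write_elevation <- function(stack, file) {
  stopifnot(inherits(stack, "climate_stack"))
  out <- data.frame(cell_id = stack$cells$cell_id, stack$elev,
                    check.names = FALSE)
  names(out)[-1L] <- sprintf("sample%03d", seq_len(ncol(stack$elev)))
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Write the pipeline output bundle to a directory
#'
#' Emits the simulated tree (newick), assemblage and cell CSVs, the metric
#' surfaces per group, the predictor table, the flattened model results and
#' a JSON manifest recording seeds, versions and the configuration hash.
#'
#' @param run a `phylogrid_run`.
#' @param outdir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_run <- function(run, outdir) {
  stopifnot(inherits(run, "phylogrid_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  ape::write.tree(run$tree, p("tree.nwk"))
  write_assemblage(run$grid, p("assemblage.csv"), p("cells.csv"))
  write_climate(run$climate, p("climate.csv"))
  for (g in names(run$metrics))
    write.csv(run$metrics[[g]], p(sprintf("metrics_%s.csv", g)),
              row.names = FALSE)
  write.csv(run$predictors, p("predictors.csv"), row.names = FALSE)
  write.csv(results_table(run), p("results.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
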