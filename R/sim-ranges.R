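#' Simulate niche-conserved species ranges on the grid
#'
#' Evolves a thermal optimum for every species by Brownian motion along the
#' phylogeny (rate `niche_signal`, ancestral state at the `root_quantile`
#' point of the current MAT field, optionally blurred by a non-heritable
#' `niche_noise` deviation) and lets each species occupy every cell whose
#' mean annual temperature lies within `niche_breadth` of its optimum.
#'
#' When `config$cold_clades > 0`, that many disjoint internal clades (of
#' `cold_clade_size` tips, never an entire root-side clade) additionally
#' inherit a large cold-ward displacement of their optima
#' (`cold_shift_frac` of the realized MAT span), with the tighter
#' `cold_clade_noise` scatter of canalized specialists. This implements the
#' tropical-niche-conservatism structure directly: cold tolerance is a rare
#' clade-level innovation in an ancestrally warm flora, so assemblages
#' become phylogenetically clustered toward the cold end of the gradient.
#'
#' When a draw leaves a species without a single occupied cell, that
#' species' optimum alone is redrawn from its Brownian terminal-branch
#' distribution (normal around its parent node's state with variance
#' `niche_signal` x pendant branch length), up to `config$max_retries`
#' times per species; the rest of the optimum vector - and hence the
#' phylogenetic structure of the trait - is left untouched. Failure after
#' the bounded retries is an error naming the species.
#'
#' @param tree an [ape::phylo] phylogeny (tips become the species pool).
#' @param climate a `climate_stack` from [simulate_climate()].
#' @param config the [sim_config()] shared by the simulation.
#' @return an object of class `grid_assemblage`: list with `pa` (cells x
#'   species 0/1 matrix, cell ids as row names), `cells` (centroid table with
#'   a `region` column initialised to NA), and `optima` (the simulated
#'   thermal optima, degC).
#' @export
simulate_ranges <- function(tree, climate, config) {
  stopifnot(inherits(tree, "phylo"), inherits(climate, "climate_stack"),
            inherits(config, "sim_config"))
  if (length(tree$tip.label) < 2L) stop_("the tree must have >= 2 tips")
  mat <- climate$current$MAT
  root_state <- as.numeric(quantile(mat, config$root_quantile))
  local_seed(child_seed(config$seed, 3L), {
    nt <- length(tree$tip.label)
    states <- ape::rTraitCont(tree, model = "BM",
                              sigma = sqrt(config$niche_signal),
                              root.value = root_state, ancestor = TRUE)
    # clade-level cold-tolerance innovations (inherited shifts)
    shift <- numeric(nt + tree$Nnode)
    if (config$cold_clades > 0) {
      span <- diff(range(mat))
      Tm <- .edge_tip_table(tree)
      csize <- rowSums(Tm)
      elig <- which(csize >= config$cold_clade_size[1L] &
                    csize <= config$cold_clade_size[2L] &
                    tree$edge[, 1L] != nt + 1L)
      if (!length(elig))
        elig <- which(csize >= 2L & csize <= floor(nt / 2) &
                      tree$edge[, 1L] != nt + 1L)
      picked <- integer(0)
      pool <- elig
      while (length(picked) < config$cold_clades && length(pool)) {
        p <- if (length(pool) == 1L) pool else
          sample(pool, 1L, prob = tree$edge.length[pool])
        picked <- c(picked, p)
        overlap <- vapply(pool, function(e)
          any(Tm[e, ] & Tm[p, ]), logical(1))
        pool <- pool[!overlap]
      }
      if (length(picked) < config$cold_clades)
        warning("only ", length(picked), " of ", config$cold_clades,
                " requested cold clades could be placed on this tree")
      frac <- config$cold_shift_frac *
        seq(1, 0.7, length.out = max(length(picked), 1L))
      for (j in seq_along(picked)) {
        J <- (frac[j] + runif(1L, -0.03, 0.03)) * span
        below <- Tm[picked[j], ]
        # every node (tip or internal) of the shifted clade: child nodes of
        # edges whose descendant tip set lies within the clade
        sub <- vapply(seq_len(nrow(tree$edge)), function(e)
          all(!Tm[e, ] | below), logical(1))
        nodes <- tree$edge[sub, 2L]
        shift[nodes] <- shift[nodes] - J
      }
    }
    states <- states + shift
    opt <- setNames(as.numeric(states[seq_len(nt)]), tree$tip.label)
    in_cold <- shift[seq_len(nt)] < 0
    noise_sd <- ifelse(in_cold, config$cold_clade_noise, config$niche_noise)
    if (any(noise_sd > 0))
      opt <- opt + rnorm(nt, 0, noise_sd)
    occupies <- function(x) abs(mat - x) <= config$niche_breadth
    # per-tip redraw of the terminal-branch deviation for empty ranges
    pendant <- tree$edge.length[match(seq_len(nt), tree$edge[, 2L])]
    parent_state <- states[tree$edge[match(seq_len(nt), tree$edge[, 2L]), 1L]]
    sdev <- sqrt(config$niche_signal * pendant + noise_sd^2)
    for (i in seq_len(nt)) {
      tries <- 0L
      while (!any(occupies(opt[i]))) {
        tries <- tries + 1L
        if (tries > config$max_retries)
          stop_("could not place species '", tree$tip.label[i],
                "' on the grid after ", config$max_retries, " redraws")
        # scale inflates every few failures so a tip whose parent state
        # lies far outside the climate span still becomes placeable; the
        # last fifth of the retry budget samples the feasible interval
        # directly
        if (tries > 0.8 * config$max_retries) {
          opt[i] <- runif(1L, min(mat) - config$niche_breadth,
                          max(mat) + config$niche_breadth)
        } else {
          opt[i] <- rnorm(1L, parent_state[i],
                          max(sdev[i], 1e-8) * 1.5^(tries %/% 5L))
        }
      }
    }
    pa <- outer(mat, opt, function(m, x) abs(m - x) <= config$niche_breadth)
    storage.mode(pa) <- "integer"
    dimnames(pa) <- list(climate$cells$cell_id, tree$tip.label)
    cells <- climate$cells
    cells$region <- NA_character_
    structure(list(pa = pa, cells = cells, optima = opt),
              class = "grid_assemblage")
  })
}

#' Assemble a grid assemblage from a presence/absence matrix
#'
#' Constructor used by file readers and tests; validates the binary matrix
#' and the centroid table.
#'
#' @param pa cells x species matrix of 0/1 presences with cell ids as row
#'   names and species ids as column names.
#' @param cells data frame with at least `cell_id`, `x_km`, `y_km`; a
#'   `region` column is added (NA) when missing.
#' @return a `grid_assemblage`.
#' @export
grid_assemblage <- function(pa, cells) {
  pa <- as.matrix(pa)
  if (!all(pa %in% c(0L, 1L)))
    stop_("the presence/absence matrix must be strictly binary")
  storage.mode(pa) <- "integer"
  if (is.null(rownames(pa)) || is.null(colnames(pa)))
    stop_("the presence/absence matrix needs cell ids as row names and ",
          "species ids as column names")
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "x_km", "y_km") %in% names(cells)))
  if (!identical(rownames(pa), as.character(cells$cell_id)))
    stop_("row names of 'pa' must match cells$cell_id in order")
  if (is.null(cells$region)) cells$region <- NA_character_
  structure(list(pa = pa, cells = cells, optima = NULL),
            class = "grid_assemblage")
}

#' @export
print.grid_assemblage <- function(x, ...) {
  cat(sprintf("Grid assemblage: %d cells x %d species, %d presences\n",
              nrow(x$pa), ncol(x$pa), sum(x$pa)))
  r <- rowSums(x$pa)
  cat(sprintf("  richness per cell: min %d, median %g, max %d\n",
              min(r), median(r), max(r)))
  invisible(x)
}
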