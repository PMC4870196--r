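# Phylogenetic assemblage metrics on a grid: PD, PE, MPD, NRI.
#
# All branch-based metrics share one clade convention: the branches counted
# for a cell are those of the subtree spanned by the cell's species, rooted
# at their most recent common ancestor, EXCLUDING the branch subtending that
# ancestor. The alternative convention that follows the path down to the
# tree root (as in Rosauer's original phylogenetic-endemism code) is exposed
# through `include_root = TRUE` everywhere.

# edge x tip indicator: which tips descend from each edge of the tree
.edge_tip_table <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")$edge
  Tm <- matrix(FALSE, nn, nt)
  Tm[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (i in seq_len(nrow(po)))
    Tm[po[i, 1L], ] <- Tm[po[i, 1L], ] | Tm[po[i, 2L], ]
  out <- Tm[tree$edge[, 2L], , drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

# shared engine: per-cell spanning-branch indicator matrix (edges x cells)
.spanning_matrix <- function(tree, pa, include_root = FALSE) {
  sp <- colnames(pa)
  unknown <- setdiff(sp, tree$tip.label)
  if (length(unknown))
    stop_("species absent from the phylogeny: ",
          paste(head(unknown, 5L), collapse = ", "),
          if (length(unknown) > 5L) ", ..." else "")
  Tm <- .edge_tip_table(tree)
  M <- matrix(0, nrow = length(tree$tip.label), ncol = nrow(pa),
              dimnames = list(tree$tip.label, rownames(pa)))
  M[sp, ] <- t(pa)
  nb <- Tm %*% M
  rich <- colSums(M)
  span <- nb >= 1
  if (!include_root) {
    lim <- matrix(rich - 1, nrow = nrow(nb), ncol = ncol(nb), byrow = TRUE)
    span <- span & nb <= lim
  }
  list(span = span, length = tree$edge.length, richness = rich)
}

#' Branches spanned by a set of tips
#'
#' Returns the indices (rows of `tree$edge`) of the branches on the paths
#' joining the given tips: the subtree rooted at their most recent common
#' ancestor, excluding the branch below that ancestor. With
#' `include_root = TRUE` the path from the ancestor down to the tree root is
#' included as well.
#'
#' @param tree an [ape::phylo] tree.
#' @param tips character vector of tip labels (at least one; a single tip
#'   spans no branches under the default convention and its own root path
#'   under `include_root = TRUE`).
#' @param include_root include the branches between the tips' common
#'   ancestor and the tree root.
#' @return sorted integer vector of edge indices.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' spanning_branches(tr, c("A", "B"))
spanning_branches <- function(tree, tips, include_root = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tips) < 1L) stop_("'tips' must name at least one tip")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop_("species absent from the phylogeny: ",
          paste(unknown, collapse = ", "))
  pa <- matrix(1L, nrow = 1L, ncol = length(tips),
               dimnames = list("cell", tips))
  s <- .spanning_matrix(tree, pa, include_root)
  sort(which(s$span[, 1L]))
}

#' Faith's phylogenetic diversity per grid cell
#'
#' PD of a cell is the summed branch length of the subtree spanned by the
#' cell's species (root branch excluded under the default convention). Cells
#' with fewer than two species have no PD value and return `NA`.
#'
#' @param tree an [ape::phylo] tree with branch lengths (Myr).
#' @param grid a `grid_assemblage`.
#' @inheritParams spanning_branches
#' @return named numeric vector of PD values (Myr), one per cell.
#' @export
compute_pd <- function(tree, grid, include_root = FALSE) {
  stopifnot(inherits(grid, "grid_assemblage"))
  s <- .spanning_matrix(tree, grid$pa, include_root)
  pd <- colSums(s$span * s$length)
  pd[s$richness < 2L] <- NA_real_
  setNames(pd, rownames(grid$pa))
}

#' Branch ranges across the grid
#'
#' For every branch of the tree, the number of grid cells whose spanning
#' branch set contains it (the range `R_c` that weights phylogenetic
#' endemism). Cells of every richness contribute under the same spanning
#' convention used for PD and PE.
#'
#' @inheritParams compute_pd
#' @return data frame with one row per tree edge: `branch` (edge index),
#'   `parent`, `child` (node numbers), `length`, `n_tips` (descendant tips)
#'   and `range` (cells).
#' @export
branch_ranges <- function(tree, grid, include_root = FALSE) {
  stopifnot(inherits(grid, "grid_assemblage"))
  s <- .spanning_matrix(tree, grid$pa, include_root)
  data.frame(branch = seq_len(nrow(tree$edge)),
             parent = tree$edge[, 1L], child = tree$edge[, 2L],
             length = tree$edge.length,
             n_tips = rowSums(.edge_tip_table(tree)),
             range = rowSums(s$span))
}

#' Phylogenetic endemism per grid cell
#'
#' PE divides every spanning branch length by the branch's range (number of
#' grid cells in which it is spanned) before summing, concentrating weight
#' on geographically restricted lineages. Summed over all cells, PE equals
#' the total length of all branches spanned anywhere - an exact conservation
#' identity that holds under either root convention. A `log1p`-transformed
#' copy is attached as attribute `"log1p"` because the endemism surface is
#' strongly right-skewed.
#'
#' @inheritParams compute_pd
#' @return named numeric vector of PE values (Myr); single-species cells are
#'   0 under the default convention. Attribute `"log1p"` holds `log(PE + 1)`.
#' @export
compute_pe <- function(tree, grid, include_root = FALSE) {
  stopifnot(inherits(grid, "grid_assemblage"))
  s <- .spanning_matrix(tree, grid$pa, include_root)
  rng <- rowSums(s$span)
  if (any(s$span & rng == 0))
    stop_("internal error: a spanned branch has zero range")
  w <- ifelse(rng > 0, s$length / rng, 0)
  pe <- colSums(s$span * w)
  pe[s$richness < 1L] <- NA_real_
  pe <- setNames(pe, rownames(grid$pa))
  attr(pe, "log1p") <- log1p(pe)
  pe
}

#' Patristic divergence matrix
#'
#' Species-by-species matrix of summed branch lengths along the paths
#' between tips; on an ultrametric tree each entry is twice the age of the
#' pair's common ancestor. Operationalizes "pairwise divergence time" for
#' MPD and NRI (whose z-score is invariant to the factor of two).
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return symmetric numeric matrix with zero diagonal (Myr).
#' @export
divergence_matrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Mean pairwise distance of a species set
#'
#' Mean of the patristic distances over all unordered pairs of distinct
#' species; `NA` when fewer than two species are supplied.
#'
#' @param dist divergence matrix from [divergence_matrix()].
#' @param tips character vector of species names.
#' @return single numeric value (Myr) or `NA`.
#' @export
compute_mpd <- function(dist, tips) {
  if (length(tips) < 2L) return(NA_real_)
  unknown <- setdiff(tips, rownames(dist))
  if (length(unknown))
    stop_("species absent from the divergence matrix: ",
          paste(unknown, collapse = ", "))
  sub <- dist[tips, tips]
  mean(sub[upper.tri(sub)])
}

#' Net relatedness index per grid cell
#'
#' Standardized effect size of the observed mean pairwise distance against a
#' null distribution obtained by drawing, `n_null` times, a random species
#' set of the same richness from the continental pool (uniform sampling
#' without replacement). The sign is flipped so that positive NRI means the
#' assemblage is MORE closely related than expected (phylogenetic
#' clustering):
#' `NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)`.
#'
#' Cells with fewer than two species, and cells whose null distribution is
#' degenerate (zero standard deviation, e.g. richness equal to the pool
#' size), return `NA`; degenerate cells are reported via `message()`.
#'
#' @param dist divergence matrix covering at least the pool.
#' @param grid a `grid_assemblage`.
#' @param n_null number of null draws per cell (>= 2; 100 by default).
#' @param pool species pool to draw from; defaults to every species in the
#'   assemblage matrix. Must contain all occurring species.
#' @param seed optional integer seed; fixed seed gives identical surfaces.
#' @return named numeric vector of NRI values (unitless z-scores).
#' @export
compute_nri <- function(dist, grid, n_null = 100, pool = NULL, seed = NULL) {
  stopifnot(inherits(grid, "grid_assemblage"))
  if (n_null < 2L) stop_("n_null must be >= 2")
  pa <- grid$pa
  pool <- pool %||% colnames(pa)
  missing_pool <- setdiff(pool, rownames(dist))
  if (length(missing_pool))
    stop_("pool species absent from the divergence matrix: ",
          paste(head(missing_pool, 5L), collapse = ", "))
  occurring <- colnames(pa)[colSums(pa) > 0]
  if (!all(occurring %in% pool))
    stop_("the pool must contain every occurring species")
  Dp <- dist[pool, pool]
  np <- length(pool)
  sp_idx <- lapply(seq_len(nrow(pa)), function(i) {
    match(colnames(pa)[pa[i, ] == 1L], pool)
  })
  local_seed(seed, {
    nri <- rep(NA_real_, nrow(pa))
    degenerate <- character(0)
    for (i in seq_len(nrow(pa))) {
      idx <- sp_idx[[i]]
      k <- length(idx)
      if (k < 2L) next
      obs <- sum(Dp[idx, idx]) / (k * (k - 1))
      sims <- numeric(n_null)
      for (j in seq_len(n_null)) {
        id <- sample.int(np, k)
        sims[j] <- sum(Dp[id, id]) / (k * (k - 1))
      }
      s <- sd(sims)
      if (s == 0) {
        degenerate <- c(degenerate, rownames(pa)[i])
        next
      }
      nri[i] <- -(obs - mean(sims)) / s
    }
    if (length(degenerate))
      message("NRI undefined (degenerate null) in ", length(degenerate),
              " cell(s): ", paste(head(degenerate, 5L), collapse = ", "))
    setNames(nri, rownames(pa))
  })
}

#' All assemblage metrics as one surface table
#'
#' Convenience wrapper computing richness, PD, PE (plus its `log1p`
#' transform), MPD and NRI for every grid cell.
#'
#' @inheritParams compute_nri
#' @param tree an [ape::phylo] tree containing all assemblage species.
#' @param include_root passed to the branch-based metrics.
#' @return data frame with columns `cell_id`, `richness`, `pd`, `pe`,
#'   `log1p_pe`, `mpd`, `nri`.
#' @export
compute_metrics <- function(tree, grid, n_null = 100, pool = NULL,
                            seed = NULL, include_root = FALSE) {
  stopifnot(inherits(grid, "grid_assemblage"))
  D <- divergence_matrix(tree)
  pe <- compute_pe(tree, grid, include_root)
  rich <- rowSums(grid$pa)
  mpd <- vapply(seq_len(nrow(grid$pa)), function(i) {
    sp <- colnames(grid$pa)[grid$pa[i, ] == 1L]
    compute_mpd(D, sp)
  }, numeric(1))
  data.frame(cell_id = rownames(grid$pa),
             richness = as.integer(rich),
             pd = unname(compute_pd(tree, grid, include_root)),
             pe = as.vector(pe),
             log1p_pe = as.vector(attr(pe, "log1p")),
             mpd = mpd,
             nri = unname(compute_nri(D, grid, n_null, pool, seed)),
             stringsAsFactors = FALSE)
}
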