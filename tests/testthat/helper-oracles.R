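# Independent brute-force oracles used against the package implementations.
# These deliberately use different algorithms (path enumeration, exhaustive
# search, definitional formulas) from the code they check.

tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# indices of the edges on the path from a tip (or node) up to the root
edges_to_root <- function(tree, node) {
  out <- integer(0)
  repeat {
    i <- which(tree$edge[, 2L] == node)
    if (!length(i)) break
    out <- c(out, i)
    node <- tree$edge[i, 1L]
  }
  out
}

# spanning branch set by explicit enumeration of all tip-pair paths
oracle_spanning <- function(tree, tips, include_root = FALSE) {
  idx <- match(tips, tree$tip.label)
  stopifnot(!anyNA(idx))
  anc <- lapply(idx, edges_to_root, tree = tree)
  if (length(idx) == 1L)
    return(if (include_root) sort(anc[[1L]]) else integer(0))
  s <- integer(0)
  for (i in seq_along(idx)) {
    for (j in seq_len(i - 1L)) {
      path <- c(setdiff(anc[[i]], anc[[j]]), setdiff(anc[[j]], anc[[i]]))
      s <- union(s, path)
    }
  }
  if (include_root) s <- union(s, Reduce(intersect, anc))
  sort(s)
}

oracle_pd <- function(tree, tips, include_root = FALSE) {
  sum(tree$edge.length[oracle_spanning(tree, tips, include_root)])
}

# patristic distance by symmetric difference of root paths
oracle_patristic <- function(tree, a, b) {
  pa <- edges_to_root(tree, match(a, tree$tip.label))
  pb <- edges_to_root(tree, match(b, tree$tip.label))
  sum(tree$edge.length[c(setdiff(pa, pb), setdiff(pb, pa))])
}

oracle_mpd <- function(tree, tips) {
  if (length(tips) < 2L) return(NA_real_)
  pairs <- utils::combn(tips, 2L)
  mean(apply(pairs, 2L, function(p) oracle_patristic(tree, p[1L], p[2L])))
}

# PE over a whole assemblage: per-cell spanning sets, branch ranges by
# direct counting, then the weighted sums
oracle_pe_surface <- function(tree, pa, include_root = FALSE) {
  sets <- lapply(seq_len(nrow(pa)), function(i) {
    sp <- colnames(pa)[pa[i, ] == 1L]
    if (length(sp) < 1L) integer(0) else
      oracle_spanning(tree, sp, include_root)
  })
  rng <- tabulate(unlist(sets), nbins = nrow(tree$edge))
  pe <- vapply(sets, function(s)
    sum(tree$edge.length[s] / rng[s]), numeric(1))
  list(pe = pe, range = rng)
}

# minimum accumulated cost from each vertex to the nearest source by
# depth-first enumeration of simple paths with branch-and-bound pruning
oracle_min_costs <- function(graph, sources) {
  n <- graph$n
  adj <- vector("list", n)
  for (r in seq_len(nrow(graph$edges))) {
    f <- graph$edges$from[r]; t <- graph$edges$to[r]
    w <- graph$edges$weight[r]
    adj[[f]] <- rbind(adj[[f]], c(t, w))
    adj[[t]] <- rbind(adj[[t]], c(f, w))
  }
  best <- rep(Inf, n)
  walk <- function(v, cost, visited) {
    if (cost >= best[v]) return(invisible())
    best[v] <<- cost
    for (r in seq_len(NROW(adj[[v]]))) {
      nxt <- adj[[v]][r, 1L]
      if (!visited[nxt]) {
        vis <- visited; vis[nxt] <- TRUE
        walk(nxt, cost + adj[[v]][r, 2L], vis)
      }
    }
  }
  for (s in sources) {
    vis <- rep(FALSE, n); vis[s] <- TRUE
    walk(s, 0, vis)
  }
  best
}

# Moran's I by the definitional double sum
oracle_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# random branch lengths on a topology, deterministic per seed
with_random_lengths <- function(tree, seed) {
  set.seed(seed)
  tree$edge.length <- runif(nrow(tree$edge), 0.1, 2)
  tree
}

# assemblage wrapper for a plain presence matrix on synthetic coordinates
as_grid <- function(pa, coords = NULL) {
  if (is.null(rownames(pa)))
    rownames(pa) <- sprintf("cell%03d", seq_len(nrow(pa)))
  if (is.null(coords))
    coords <- cbind(x_km = seq_len(nrow(pa)) * 10, y_km = 0)
  grid_assemblage(pa, data.frame(cell_id = rownames(pa),
                                 x_km = coords[, 1L], y_km = coords[, 2L],
                                 stringsAsFactors = FALSE))
}

# the frozen strong-niche-conservatism study condition (see methods vignette)
tnc_config <- function(seed) {
  sim_config(n_tips = 150, grid_rows = 20, grid_cols = 20,
             gradient_strength = 0.5, noise_sd = 0.5,
             niche_signal = 0, niche_noise = 1.2, niche_breadth = 1.5,
             root_quantile = 0.9, cold_clades = 1,
             cold_clade_size = c(7, 10), cold_shift_frac = 0.65,
             cold_clade_noise = 0.5, seed = seed)
}

tnc_spearman <- function(seed, n_null = 60) {
  cfg <- tnc_config(seed)
  tr <- simulate_phylogeny(cfg)
  cl <- simulate_climate(cfg)
  gr <- simulate_ranges(tr, cl, cfg)
  keep <- rowSums(gr$pa) >= 5
  sub <- gr
  sub$pa <- gr$pa[keep, , drop = FALSE]
  sub$cells <- gr$cells[keep, ]
  nri <- suppressMessages(compute_nri(divergence_matrix(tr), sub,
                                      n_null = n_null, seed = 1000 + seed))
  suppressWarnings(cor(nri, cl$current$MAT[keep], method = "spearman",
                       use = "complete.obs"))
}
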