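#' Simulate an ultrametric birth-death phylogeny
#'
#' Forward-simulates a crown birth-death process until the number of coeval
#' lineages first reaches `n_tips`, extends the present by one further
#' exponential waiting time (so no pendant branch has zero length), prunes
#' extinct lineages, and returns the reconstructed tree. Under a pure-birth
#' process the expected crown depth of the returned tree is
#' `(H(n) - 1) / birth_rate` with `H(n)` the n-th harmonic number, which the
#' test suite uses as a closed-form oracle.
#'
#' Branch lengths are in Myr. The tree is rooted, binary, ultrametric, and
#' deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object (`n_tips >= 2`,
#'   `death_rate < birth_rate`).
#' @return an [ape::phylo] tree with exactly `config$n_tips` tips labelled
#'   `s001`, `s002`, ...
#' @export
#' @examples
#' tr <- simulate_phylogeny(sim_config(n_tips = 10, seed = 7))
#' ape::is.ultrametric(tr)
simulate_phylogeny <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_tips
  if (n < 2) stop_("n_tips must be >= 2")
  if (config$death_rate >= config$birth_rate)
    stop_("death_rate must be < birth_rate")
  local_seed(child_seed(config$seed, 1L), {
    tr <- NULL
    for (attempt in seq_len(10000L)) {
      tr <- .sim_bd_once(n, config$birth_rate, config$death_rate)
      if (!is.null(tr)) break
    }
    if (is.null(tr))
      stop_("birth-death simulation went extinct in every attempt")
    tr
  })
}

# One conditioned birth-death realization; NULL when the crown clade dies.
.sim_bd_once <- function(n, b, d) {
  parent <- c(0L, 0L)
  t_start <- c(0, 0)
  t_end <- c(NA_real_, NA_real_)
  fate <- c(NA_integer_, NA_integer_) # 1 speciated, 2 extinct, 3 extant
  active <- c(1L, 2L)
  t <- 0
  rate1 <- b + d
  while (length(active) != n) {
    m <- length(active)
    if (m == 0L) return(NULL)
    t <- t + rexp(1L, m * rate1)
    i <- active[sample.int(m, 1L)]
    t_end[i] <- t
    if (runif(1L) < b / rate1) {
      fate[i] <- 1L
      id <- length(parent) + c(1L, 2L)
      parent <- c(parent, i, i)
      t_start <- c(t_start, t, t)
      t_end <- c(t_end, NA_real_, NA_real_)
      fate <- c(fate, NA_integer_, NA_integer_)
      active <- c(active[active != i], id)
    } else {
      fate[i] <- 2L
      active <- active[active != i]
    }
  }
  # stop just before the next event so every pendant branch is positive
  present <- t + rexp(1L, n * rate1)
  t_end[active] <- present
  fate[active] <- 3L
  tr <- .lineages_to_phylo(parent, t_start, t_end, fate)
  extinct <- tr$tip.label[grepl("^x", tr$tip.label)]
  if (length(extinct))
    tr <- ape::drop.tip(tr, extinct)
  tr$tip.label <- sprintf("s%03d", seq_len(length(tr$tip.label)))
  tr
}

# Convert the lineage table of the event simulation into an ape phylo.
# Extinct tips are labelled x<k> so the caller can prune them.
.lineages_to_phylo <- function(parent, t_start, t_end, fate) {
  is_tip <- fate != 1L
  ntip <- sum(is_tip)
  nlin <- length(parent)
  node_id <- integer(nlin)
  node_id[is_tip] <- seq_len(ntip)
  node_id[!is_tip] <- ntip + 1L + seq_len(sum(!is_tip))
  from <- integer(nlin)
  from[parent == 0L] <- ntip + 1L
  has_par <- parent > 0L
  from[has_par] <- node_id[parent[has_par]]
  edge <- cbind(from, node_id)
  lab <- character(ntip)
  lab[fate[is_tip] == 3L] <- sprintf("e%d", seq_len(sum(fate[is_tip] == 3L)))
  lab[fate[is_tip] == 2L] <- sprintf("x%d", seq_len(sum(fate[is_tip] == 2L)))
  tr <- structure(list(edge = edge,
                       edge.length = t_end - t_start,
                       tip.label = lab,
                       Nnode = sum(!is_tip) + 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Root-to-tip depths of a rooted tree
#'
#' Utility used by ultrametry checks and by the niche simulator: the summed
#' branch length from the root to every tip.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return named numeric vector of depths, one per tip.
#' @export
tip_depths <- function(tree) {
  nt <- length(tree$tip.label)
  depth <- numeric(nt + tree$Nnode)
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  len <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edge)))
    depth[edge[i, 2L]] <- depth[edge[i, 1L]] + len[i]
  setNames(depth[seq_len(nt)], tree$tip.label)
}
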