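# Synthetic-data generator: phylogeny, climate, ranges, SAR responses.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_tips = 0), "count")
  expect_error(sim_config(birth_rate = 0.1, death_rate = 0.1), "death_rate")
  expect_error(sim_config(birth_rate = 0.1, death_rate = 0.3), "death_rate")
  expect_error(sim_config(niche_breadth = 0), "niche_breadth")
  expect_error(sim_config(root_quantile = 1.2), "root_quantile")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("a two-tip tree has two equal pendant branches", {
  tr <- simulate_phylogeny(sim_config(n_tips = 2, seed = 5))
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(nrow(tr$edge), 2L)
  expect_equal(tr$edge.length[1L], tr$edge.length[2L])
})

test_that("the phylogeny simulator is deterministic under the seed", {
  cfg <- sim_config(n_tips = 50, seed = 1)
  n1 <- ape::write.tree(simulate_phylogeny(cfg))
  n2 <- ape::write.tree(simulate_phylogeny(cfg))
  expect_identical(n1, n2)
  n3 <- ape::write.tree(simulate_phylogeny(sim_config(n_tips = 50, seed = 2)))
  expect_false(identical(n1, n3))
})

test_that("simulated trees are ultrametric with the requested tip count", {
  for (s in 1:5) {
    cfg <- sim_config(n_tips = 40, death_rate = 0.08, seed = s)
    tr <- simulate_phylogeny(cfg)
    expect_equal(length(tr$tip.label), 40L)
    expect_true(all(tr$edge.length > 0))
    d <- tip_depths(tr)
    expect_lt(max(d) - min(d), 1e-9 * max(d))
  }
})

test_that("pure-birth crown depth matches the harmonic-sum expectation", {
  # stopping just before the event after the n-th lineage arises gives
  # E[crown depth] = (H_n - 1) / birth_rate
  n <- 200; b <- 1
  expected <- (sum(1 / seq_len(n)) - 1) / b
  depths <- vapply(1:100, function(s) {
    tr <- simulate_phylogeny(sim_config(n_tips = n, birth_rate = b,
                                        death_rate = 0, seed = s))
    max(tip_depths(tr))
  }, numeric(1))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 4 * se + 0.05)
})

test_that("zero-noise climate is exactly linear in the row index", {
  cfg <- sim_config(grid_rows = 8, grid_cols = 6, noise_sd = 0,
                    gradient_strength = 0.7, seed = 3)
  cl <- simulate_climate(cfg)
  expect_equal(cl$current$MAT, 25 - 0.7 * (cl$cells$row - 1))
  m <- layer_matrix(cl, "MAT")
  expect_true(all(diff(m[, 1L]) < 0))  # monotone cooling along rows
})

test_that("zero LGM offset and zero anomaly reproduce the current field", {
  cfg <- sim_config(lgm_offset = 0, anomaly_amp = 0, seed = 4,
                    grid_rows = 6, grid_cols = 6)
  cl <- simulate_climate(cfg)
  expect_equal(cl$lgm$MAT_lgm, cl$current$MAT)
})

test_that("the climate stack is deterministic and fully populated", {
  cfg <- sim_config(grid_rows = 5, grid_cols = 7, seed = 11)
  c1 <- simulate_climate(cfg)
  c2 <- simulate_climate(cfg)
  expect_identical(c1, c2)
  expect_gte(ncol(c1$bioclim), 19L)
  expect_false(anyNA(c1$current))
  expect_false(anyNA(c1$lgm))
  expect_error(simulate_climate(sim_config(grid_rows = 2)), "3 x 3")
})

test_that("infinite niche breadth fills the grid completely", {
  cfg <- sim_config(n_tips = 10, grid_rows = 5, grid_cols = 5,
                    niche_breadth = Inf, seed = 2)
  tr <- simulate_phylogeny(cfg)
  gr <- simulate_ranges(tr, simulate_climate(cfg), cfg)
  expect_true(all(gr$pa == 1L))
})

test_that("zero niche signal collapses all optima onto the root state", {
  cfg <- sim_config(n_tips = 12, grid_rows = 6, grid_cols = 6,
                    niche_signal = 0, niche_noise = 0, seed = 9)
  cl <- simulate_climate(cfg)
  gr <- simulate_ranges(simulate_phylogeny(cfg), cl, cfg)
  root <- as.numeric(quantile(cl$current$MAT, cfg$root_quantile))
  expect_true(all(abs(gr$optima - root) < 1e-12))
  expect_true(all(gr$pa == gr$pa[, 1L]))  # identical ranges
})

test_that("assemblages are binary with occupied rows and columns", {
  cfg <- sim_config(seed = 21)
  gr <- simulate_ranges(simulate_phylogeny(cfg), simulate_climate(cfg), cfg)
  expect_true(all(gr$pa %in% c(0L, 1L)))
  expect_true(all(colSums(gr$pa) >= 1))
  expect_true(all(rowSums(gr$pa) >= 1))
  g2 <- simulate_ranges(simulate_phylogeny(cfg), simulate_climate(cfg), cfg)
  expect_identical(gr$pa, g2$pa)
})

test_that("strong niche signal sorts clades along the gradient", {
  # two deep clades; the cold end should be dominated by one of them
  tr <- ape::read.tree(text = paste0(
    "(((a1:1,a2:1):1,(a3:1,a4:1):1):8,",
    "((b1:1,b2:1):1,(b3:1,b4:1):1):8);"))
  cfg <- sim_config(n_tips = 8, grid_rows = 12, grid_cols = 6,
                    gradient_strength = 1, niche_signal = 2,
                    niche_breadth = 2.5, root_quantile = 0.5, seed = 1)
  cl <- simulate_climate(cfg)
  gr <- simulate_ranges(tr, cl, cfg)
  occupied <- rowSums(gr$pa) > 0
  cold <- which(occupied)[order(cl$current$MAT[occupied])][1:6]
  counts <- colSums(gr$pa[cold, , drop = FALSE])
  cladeA <- sum(counts[startsWith(names(counts), "a")])
  purity <- max(cladeA, sum(counts) - cladeA) / sum(counts)
  expect_gt(purity, 0.7)
})

test_that("phylogenetic signal of optima rises with the Brownian rate", {
  skip_if_not_installed("phytools")
  rates <- c(0.05, 0.5, 5)
  mean_lambda <- vapply(rates, function(r) {
    lam <- vapply(1:25, function(s) {
      cfg <- sim_config(n_tips = 40, niche_signal = r, niche_noise = 0.5,
                       niche_breadth = Inf, seed = s)
      tr <- simulate_phylogeny(cfg)
      gr <- simulate_ranges(tr, simulate_climate(cfg), cfg)
      ps <- phytools::phylosig(tr, gr$optima, method = "lambda")
      ps$lambda
    }, numeric(1))
    mean(lam)
  }, numeric(1))
  expect_identical(order(mean_lambda), seq_along(rates))
})

test_that("cold-clade innovations displace whole clades coldward", {
  cfg <- tnc_config(3)
  tr <- simulate_phylogeny(cfg)
  cl <- simulate_climate(cfg)
  gr <- simulate_ranges(tr, cl, cfg)
  o <- gr$optima
  shifted <- names(o)[o < quantile(cl$current$MAT, 0.25)]
  expect_gte(length(shifted), cfg$cold_clade_size[1L])
  # the cold species form a connected clade: their spanning subtree
  # contains (almost) no other species
  mrca_tips <- ape::extract.clade(tr, ape::getMRCA(tr, shifted))$tip.label
  expect_lte(length(setdiff(mrca_tips, shifted)), 2L)
})

test_that("SAR responses follow y = X beta + (I - lambda W)^-1 eps", {
  set.seed(42)
  coords <- matrix(runif(60) * 100, ncol = 2)
  w <- knn_weights(coords, 4)
  X <- cbind(1, rnorm(30))
  beta <- c(2, -1)
  expect_equal(simulate_sar_response(X, w, beta, lambda = 0, sigma = 0),
               drop(X %*% beta))
  y1 <- simulate_sar_response(X, w, beta, lambda = 0.5, sigma = 1, seed = 3)
  y2 <- simulate_sar_response(X, w, beta, lambda = 0.5, sigma = 1, seed = 3)
  expect_identical(y1, y2)
  expect_error(simulate_sar_response(X, w, beta, lambda = 1, sigma = 1),
               "lambda")
})

test_that("SAR errors with positive lambda are spatially autocorrelated", {
  set.seed(10)
  coords <- matrix(runif(800) * 1000, ncol = 2)
  w <- knn_weights(coords, 5)
  X <- matrix(0, 400, 1)
  hits <- vapply(1:30, function(s) {
    u <- simulate_sar_response(X, w, 0, lambda = 0.7, sigma = 1, seed = s)
    oracle_moran(u, w$W) > -1 / 399
  }, logical(1))
  expect_gte(sum(hits), 29)
})

test_that("the LGM forest envelope rule behaves at its limits", {
  cfg <- sim_config(grid_rows = 6, grid_cols = 6, seed = 8)
  cl <- simulate_climate(cfg)
  expect_true(all(make_lgm_forest_mask(cl, list(MAT_lgm = c(-Inf, Inf)))))
  expect_error(make_lgm_forest_mask(cl, list(MAT_lgm = c(1e6, Inf))),
               "accessibility")
  q <- as.numeric(quantile(cl$lgm$MAT_lgm, 0.25))
  mask <- make_lgm_forest_mask(cl, list(MAT_lgm = c(q, Inf)))
  expect_equal(sum(mask), sum(cl$lgm$MAT_lgm >= q))  # linear-scan oracle
})
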