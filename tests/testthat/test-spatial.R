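# kNN weights, Moran's I, the SAR-error ML fit, collinearity grouping,
# candidate enumeration, model averaging and k selection.

test_that("kNN weights are row-standardized with tie-broken neighbours", {
  pts <- cbind(c(0, 1, 2), 0)
  w <- knn_weights(pts, 1)
  # endpoints pick the middle; the equidistant middle point takes the
  # lower-index endpoint under the documented tie rule
  expect_equal(w$neighbors[, 1L], c(2L, 1L, 2L))
  expect_true(all(abs(rowSums(w$W) - 1) < 1e-12))
  expect_true(all(diag(w$W) == 0))
  expect_error(knn_weights(pts, 3), "k")
})

test_that("neighbour sets match a brute-force sort of the distances", {
  set.seed(8)
  pts <- matrix(runif(10), 5, 2)
  w <- knn_weights(pts, 2)
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  for (i in 1:5)
    expect_setequal(w$neighbors[i, ], order(d[i, ])[1:2])
})

test_that("Moran's I follows its definitional formula and null moments", {
  set.seed(9)
  pts <- matrix(runif(80) * 100, 40, 2)
  w <- knn_weights(pts, 5)
  x <- rnorm(40)
  mt <- morans_i(x, w)
  expect_equal(mt$statistic, oracle_moran(x, w$W), tolerance = 1e-12)
  expect_equal(mt$expectation, -1 / 39)
  expect_true(is.na(morans_i(rep(1, 40), w)$statistic))
  # iid values: the empirical mean of I approaches -1/(n-1)
  set.seed(10)
  pts <- matrix(runif(200) * 100, 100, 2)
  w <- knn_weights(pts, 5)
  sims <- replicate(200, morans_i(rnorm(100), w)$statistic)
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) + 1 / 99), 4 * se)
})

test_that("Moran's I is signed by the spatial pattern", {
  gridpts <- as.matrix(expand.grid(x = 1:8, y = 1:8))
  w <- knn_weights(gridpts, 4)  # rook neighbourhood on the unit grid
  checker <- (-1)^(gridpts[, 1L] + gridpts[, 2L])
  expect_lt(morans_i(checker, w)$statistic, 0)
  smooth <- gridpts[, 1L] + gridpts[, 2L]
  expect_gt(morans_i(smooth, w)$statistic, 0)
})

test_that("the SAR fit with lambda fixed at zero reproduces OLS exactly", {
  set.seed(11)
  coords <- matrix(runif(400) * 1000, 200, 2)
  w <- knn_weights(coords, 5)
  X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1 + X %*% c(0.8, -0.4) + rnorm(200)
  fit <- fit_sar_error(y, X, w, lambda_fixed = 0, standardize = FALSE)
  ols <- lm(y ~ X)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(fit$ols_r2_adj, summary(ols)$adj.r.squared,
               tolerance = 1e-10)
})

test_that("the profile likelihood peaks at the returned optimum", {
  set.seed(12)
  coords <- matrix(runif(400) * 1000, 200, 2)
  w <- knn_weights(coords, 5)
  X <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "a"))
  y <- simulate_sar_response(cbind(1, X), w, c(0.3, 1), 0.6, 1, seed = 3)
  fit <- fit_sar_error(y, X, w, standardize = FALSE)
  expect_lt(abs(fit$lambda - 0.6), 0.25)
  relik <- function(l) fit_sar_error(y, X, w, lambda_fixed = l,
                                     standardize = FALSE)$logLik
  for (d in c(-0.05, -0.01, 0.01, 0.05))
    expect_gte(fit$logLik, relik(fit$lambda + d))
  expect_equal(fit$aic, -2 * fit$logLik + 2 * (ncol(X) + 1 + 2))
})

test_that("standardized fits report standardized effect sizes", {
  set.seed(13)
  coords <- matrix(runif(300) * 100, 150, 2)
  w <- knn_weights(coords, 4)
  X <- matrix(rnorm(300), 150, 2, dimnames = list(NULL, c("a", "b")))
  y <- X %*% c(5, 0) + rnorm(150, 0, 0.5)
  fit <- fit_sar_error(y, X, w)
  expect_lt(abs(fit$coefficients[["a"]]) , 1.05)
  expect_gt(abs(fit$coefficients[["a"]]), 0.8)
  expect_error(fit_sar_error(y, cbind(X, c = 1), w), "constant")
  expect_error(fit_sar_error(y, cbind(X, a2 = X[, 1]), w,
                             standardize = FALSE), "alias")
})

test_that("AIC ranking ignores predictor column order", {
  set.seed(14)
  coords <- matrix(runif(240) * 100, 120, 2)
  w <- knn_weights(coords, 4)
  X <- matrix(rnorm(360), 120, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -1, 0.5) + rnorm(120)
  f1 <- fit_sar_error(y, X, w)
  f2 <- fit_sar_error(y, X[, c(3, 1, 2)], w)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("collinearity grouping is transitive over the threshold graph", {
  skip_if_not_installed("MASS")
  Sigma <- matrix(c(1, 0.9, 0.2,
                    0.9, 1, 0.6,
                    0.2, 0.6, 1), 3, 3,
                  dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  set.seed(15)
  X <- MASS::mvrnorm(100, rep(0, 3), Sigma, empirical = TRUE)
  colnames(X) <- c("A", "B", "C")
  g <- collinearity_groups(X)
  expect_length(g, 1L)
  expect_setequal(g[[1L]], c("A", "B", "C"))
  # all |r| <= 0.5: no groups
  set.seed(16)
  X0 <- MASS::mvrnorm(100, rep(0, 3), diag(3), empirical = TRUE)
  colnames(X0) <- c("A", "B", "C")
  expect_length(collinearity_groups(X0), 0L)
  expect_error(collinearity_groups(cbind(X, k = 1)), "constant")
})

test_that("the predictor set splits into the temperature/accessibility and
           stability groups under the reference correlation structure", {
  # factor structure mirroring the published correlation pattern: one
  # latent temperature axis behind MAT, TMIN, TES (negative) and ACC,
  # one latent stability axis behind VT and EHET, WBL and PRS free
  set.seed(17)
  n <- 500
  Tm <- rnorm(n); S <- rnorm(n)
  X <- cbind(MAT = Tm + 0.3 * rnorm(n),
             TMIN = Tm + 0.3 * rnorm(n),
             TES = -Tm + 0.5 * rnorm(n),
             ACC = Tm + 0.4 * rnorm(n),
             VT = S + 0.5 * rnorm(n),
             EHET = S + 0.5 * rnorm(n),
             WBL = rnorm(n),
             PRS = rnorm(n))
  g <- collinearity_groups(X, threshold = 0.5)
  expect_length(g, 2L)
  sizes <- sort(lengths(g))
  expect_equal(sizes, c(2L, 4L))
  expect_setequal(g[[which(lengths(g) == 4L)]],
                  c("MAT", "TMIN", "TES", "ACC"))
  expect_setequal(g[[which(lengths(g) == 2L)]], c("VT", "EHET"))
  cand <- enumerate_candidates(colnames(X), g)
  expect_equal(attr(cand, "n_full"), 8L)
  expect_length(cand, 59L)
})

test_that("candidate enumeration deduplicates across full-model lattices", {
  cand <- enumerate_candidates(c("a", "b", "c"), list())
  expect_length(cand, 7L)  # 2^3 - 1
  g <- list(c("g1a", "g1b", "g1c", "g1d"), c("g2a", "g2b"))
  cand2 <- enumerate_candidates(c(unlist(g), "f1", "f2"), g)
  expect_equal(attr(cand2, "n_full"), 8L)
  expect_length(cand2, (4 + 1) * (2 + 1) * 4 - 1)   # 59 distinct models
  keys <- vapply(cand2, function(v) paste(sort(v), collapse = "|"), "")
  expect_false(anyDuplicated(keys) > 0)
  expect_error(enumerate_candidates(c("a", "b"),
                                    list(c("a", "b"), c("b"))), "disjoint")
})

test_that("model averaging matches a hand-computed spreadsheet example", {
  fake <- function(aic, beta) {
    structure(list(aic = aic,
                   coefficients = c(`(Intercept)` = 0, beta),
                   predictors = names(beta)), class = "sar_fit")
  }
  fits <- list(fake(100, c(x = 0.5, z = 0.2)),
               fake(102, c(x = 0.3)),
               fake(120, c(z = 9)))           # outside the dAIC window
  avg <- model_average(fits, delta_max = 10)
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  tab <- avg$table
  expect_equal(tab$coefficient[tab$predictor == "x"],
               w[1] * 0.5 + w[2] * 0.3)
  expect_equal(tab$coefficient[tab$predictor == "z"], w[1] * 0.2)
  expect_equal(tab$importance[tab$predictor == "x"], 1)
  expect_equal(tab$importance[tab$predictor == "z"], w[1])
  expect_equal(sum(avg$models$weight, na.rm = TRUE), 1)
  expect_false(avg$models$retained[3L])
  # conditional averaging divides by the weight of containing models
  avgc <- model_average(fits, delta_max = 10, conditional = TRUE)
  expect_equal(avgc$table$coefficient[avgc$table$predictor == "z"], 0.2)
})

test_that("degenerate averaging cases behave as contracts demand", {
  fake <- function(aic, beta) {
    structure(list(aic = aic,
                   coefficients = c(`(Intercept)` = 0, beta),
                   predictors = names(beta)), class = "sar_fit")
  }
  single <- model_average(list(fake(50, c(x = 1.5))))
  expect_equal(single$table$coefficient, 1.5)
  expect_equal(single$table$importance, 1)
  twins <- model_average(list(fake(60, c(x = 1)), fake(60, c(y = 2))))
  expect_equal(twins$models$weight, c(0.5, 0.5))
})

test_that("k selection walks down from k_start and flags failure", {
  set.seed(18)
  coords <- matrix(runif(300) * 1000, 150, 2)
  X <- matrix(rnorm(300), 150, 2, dimnames = list(NULL, c("a", "b")))
  y <- X %*% c(1, -1) + rnorm(150)          # spatially white residuals
  sel <- select_k(y, X, coords)
  expect_equal(sel$k, 10)
  expect_true(sel$whitened)
  expect_equal(nrow(sel$trace), 1L)
  # impossible alpha: no k can pass, fall back to k_min with a warning
  expect_warning(sel4 <- select_k(y, X, coords, alpha = 1 + 1e-9),
                 "k = 4")
  expect_equal(sel4$k, 4)
  expect_false(sel4$whitened)
  expect_equal(sel4$trace$k, 10:4)
})
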