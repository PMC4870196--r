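# End-to-end orchestration: simulate -> metrics -> predictors -> models.

#' Assign grid cells to forest regions
#'
#' The built-in `"latitude_thirds"` rule labels the top third of the grid
#' (largest `y_km`) as `north` and splits the remainder at the median
#' longitude into `west` and `east` - a synthetic stand-in for ecoregion
#' membership. `"single"` labels every cell `all`. A custom rule may be
#' supplied as a function of the cell table returning one label per cell
#' (the label `nonforest` marks cells excluded from every regional model);
#' leaving any cell unlabelled is an error.
#'
#' @param cells cell table with `x_km`, `y_km`.
#' @param rule `"latitude_thirds"`, `"single"`, or a function.
#' @return character vector of region labels.
#' @export
assign_regions <- function(cells, rule = "latitude_thirds") {
  lab <- if (is.function(rule)) {
    as.character(rule(cells))
  } else if (identical(rule, "latitude_thirds")) {
    y_cut <- quantile(cells$y_km, 2 / 3)
    north <- cells$y_km > y_cut
    x_cut <- median(cells$x_km[!north])
    ifelse(north, "north", ifelse(cells$x_km <= x_cut, "west", "east"))
  } else if (identical(rule, "single")) {
    rep("all", nrow(cells))
  } else stop_("unknown region rule")
  if (length(lab) != nrow(cells) || anyNA(lab))
    stop_("the region rule left cells unlabelled")
  lab
}

# the internal edge whose clade is closest to half the tips; returns the
# two complementary species sets (larger first)
.split_groups <- function(tree) {
  Tm <- .edge_tip_table(tree)
  nt <- ncol(Tm)
  sizes <- rowSums(Tm)
  internal <- which(sizes >= 2L & sizes <= nt - 2L)
  if (!length(internal)) internal <- which(sizes >= 1L & sizes <= nt - 1L)
  best <- internal[which.min(abs(sizes[internal] - nt / 2))]
  inside <- colnames(Tm)[Tm[best, ]]
  outside <- setdiff(tree$tip.label, inside)
  if (length(inside) >= length(outside))
    list(A = inside, B = outside)
  else
    list(A = outside, B = inside)
}

#' Configuration of a full pipeline run
#'
#' Collects the simulation settings and every analysis option of
#' [run_all()]. Defaults describe the reference synthetic study: a 30x30
#' grid of 100-km cells, 60 species, two species groups (the two most
#' balanced complementary clades of the tree, the angiosperm/gymnosperm
#' analog), richness filters of >= 5 species per cell for the larger group
#' and >= 2 for the smaller, 100 randomizations per NRI cell, and the
#' standard model battery per group x region x response.
#'
#' @param sim a [sim_config()]; the default reference study uses 60 species
#'   on a 30x30 grid with a mid-gradient ancestral optimum and a 4 degC
#'   tolerance half-width, chosen so both species groups span all three
#'   forest regions and every regional model is estimable.
#' @param n_null NRI null draws per cell.
#' @param min_richness length-2 vector: minimum per-cell species richness
#'   for modelling, larger group first (defaults `c(5, 2)`); both >= 2.
#' @param delta_max AIC retention window for averaging.
#' @param alpha significance level of the residual Moran test.
#' @param k_start,k_min search range for the spatial-weights k.
#' @param cor_threshold absolute-correlation threshold for collinearity
#'   grouping.
#' @param region_rule passed to [assign_regions()].
#' @param responses metric columns modelled (subset of
#'   `c("pd", "nri", "log1p_pe")`).
#' @param forest_rule envelope rule for [make_lgm_forest_mask()]; the
#'   default marks cells in the warmest three quarters of the LGM MAT field
#'   as glacial forest sources.
#' @param connectivity cost-graph neighbourhood (8 or 4).
#' @param include_root branch convention for PD/PE (see [compute_pd()]).
#' @param seed master seed; stage seeds are derived deterministically.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = NULL, n_null = 100, min_richness = c(5, 2),
                       delta_max = 10, alpha = 0.05, k_start = 10,
                       k_min = 4, cor_threshold = 0.5,
                       region_rule = "latitude_thirds",
                       responses = c("pd", "nri", "log1p_pe"),
                       forest_rule = NULL, connectivity = 8,
                       include_root = FALSE, seed = 1) {
  sim <- sim %||% sim_config(n_tips = 60, grid_rows = 30, grid_cols = 30,
                             root_quantile = 0.5, niche_breadth = 4,
                             seed = seed)
  stopifnot(inherits(sim, "sim_config"))
  if (length(min_richness) != 2L || any(min_richness < 2))
    stop_("min_richness must be two values >= 2 (PD and NRI are undefined ",
          "below two species)")
  responses <- match.arg(responses, c("pd", "nri", "log1p_pe"),
                         several.ok = TRUE)
  structure(list(sim = sim, n_null = n_null,
                 min_richness = c(A = min_richness[1L], B = min_richness[2L]),
                 delta_max = delta_max, alpha = alpha, k_start = k_start,
                 k_min = k_min, cor_threshold = cor_threshold,
                 region_rule = region_rule, responses = responses,
                 forest_rule = forest_rule, connectivity = connectivity,
                 include_root = include_root, seed = seed),
            class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates the study system (phylogeny, climate, ranges), splits the
#' species into two clade-based groups, computes the assemblage metrics per
#' group, derives the predictor table (WBL, EHET, VT, ACC and the current
#' climate variables), and fits the SAR-error multimodel battery for every
#' group x region x response combination: collinearity grouping, candidate
#' enumeration, k selection by residual Moran's I, AIC-window averaging.
#' Cells excluded from a model carry a reason code (`nonforest`,
#' `below_richness_filter`, `undefined_metric`); candidate fits whose
#' lambda estimate lands on the search boundary are counted per model in
#' `n_boundary_fits` instead of raising individual warnings. Rerunning
#' with the same configuration reproduces the outputs exactly.
#'
#' @param config a [run_config()].
#' @param outdir optional directory; when given, all tables, the newick
#'   tree and a manifest are written there as plain text.
#' @param verbose print stage progress.
#' @return object of class `phylogrid_run`: list with the simulated inputs,
#'   `metrics` (per group), `predictors`, `models` (per combination: the
#'   averaging result, chosen k, Moran p, best-model OLS adjusted R2, cell
#'   log), and `manifest`.
#' @export
run_all <- function(config, outdir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  t0 <- proc.time()[["elapsed"]]

  say("stage 1/4: simulating phylogeny, climate and ranges")
  tree <- simulate_phylogeny(config$sim)
  climate <- simulate_climate(config$sim)
  grid <- simulate_ranges(tree, climate, config$sim)
  grid$cells$region <- assign_regions(grid$cells, config$region_rule)
  groups <- .split_groups(tree)

  say("stage 2/4: assemblage metrics per group (",
      length(groups$A), " + ", length(groups$B), " species)")
  metrics <- list()
  for (g in c("A", "B")) {
    sp <- groups[[g]]
    sub <- grid
    sub$pa <- grid$pa[, sp, drop = FALSE]
    subtree <- ape::keep.tip(tree, sp)
    metrics[[g]] <- compute_metrics(
      subtree, sub, n_null = config$n_null, pool = sp,
      seed = child_seed(config$seed, if (g == "A") 4L else 5L),
      include_root = config$include_root)
  }

  say("stage 3/4: paleo predictors (velocity, accessibility, EHET)")
  vt <- temperature_velocity(layer_matrix(climate, "MAT"),
                             layer_matrix(climate, "MAT_lgm"),
                             cell_size = climate$cell_size)
  forest_rule <- config$forest_rule %||%
    list(MAT_lgm = c(as.numeric(quantile(climate$lgm$MAT_lgm, 0.75)), Inf))
  mask <- make_lgm_forest_mask(climate, forest_rule)
  pca <- climate_pca(climate$bioclim, 3)
  graph <- climate_cost_graph(pca$scores, climate$cells,
                              config$connectivity)
  accd <- least_cost_accessibility(graph, mask)
  ehet <- elevation_heterogeneity(climate$elev)
  ptab <- build_predictor_table(climate, accd$acc, cell_vector(vt), ehet)

  say("stage 4/4: SAR-error multimodel battery")
  pred_names <- c("MAT", "TMIN", "TES", "WBL", "PRS", "EHET", "VT", "ACC")
  regions <- c("continental", sort(setdiff(unique(grid$cells$region),
                                           "nonforest")))
  wcache <- new.env(parent = emptyenv())
  models <- list()
  cell_log <- list()
  for (g in c("A", "B")) {
    met <- metrics[[g]]
    minr <- config$min_richness[[g]]
    for (reg in regions) {
      in_region <- if (reg == "continental")
        grid$cells$region != "nonforest" else grid$cells$region == reg
      for (resp in config$responses) {
        y_all <- met[[resp]]
        reason <- rep(NA_character_, nrow(met))
        reason[!in_region] <- "nonforest_or_other_region"
        low <- in_region & met$richness < minr
        reason[low] <- "below_richness_filter"
        bad <- in_region & !low & (is.na(y_all) |
          !complete.cases(ptab[, pred_names]))
        reason[bad] <- "undefined_metric"
        use <- in_region & !low & !bad
        key <- paste(g, reg, resp, sep = ".")
        cell_log[[key]] <- data.frame(cell_id = met$cell_id, used = use,
                                      reason = reason,
                                      stringsAsFactors = FALSE)
        entry <- list(group = g, region = reg, response = resp,
                      n_cells = sum(use))
        need <- max(config$k_start + 2L, length(pred_names) + 4L)
        if (sum(use) < need) {
          if (reg == "continental" && !any(use) &&
              all(reason[in_region] == "below_richness_filter",
                  na.rm = TRUE))
            stop_("richness filter (>= ", minr, " species) removed every ",
                  "cell for group ", g)
          entry$status <- "insufficient_cells"
          models[[key]] <- entry
          next
        }
        y <- y_all[use]
        X <- as.matrix(ptab[use, pred_names])
        coords <- as.matrix(grid$cells[use, c("x_km", "y_km")])
        # a predictor constant within this cell subset carries no
        # information for this model; drop it and record the fact
        const <- apply(X, 2L, sd) == 0
        dropped <- colnames(X)[const]
        X <- X[, !const, drop = FALSE]
        cgroups <- collinearity_groups(X, config$cor_threshold)
        cand <- enumerate_candidates(colnames(X), cgroups)
        n_boundary <- 0L
        fits <- withCallingHandlers({
          sel <- .select_k_cached(y, X, coords, config, wcache)
          lapply(cand, function(v)
            fit_sar_error(y, X[, v, drop = FALSE], sel$weights))
        }, warning = function(w) {
          if (grepl("search boundary", conditionMessage(w))) {
            n_boundary <<- n_boundary + 1L
            invokeRestart("muffleWarning")
          }
        })
        avg <- model_average(fits, config$delta_max)
        best <- fits[[avg$best]]
        entry <- c(entry, list(
          status = "ok", dropped_predictors = dropped,
          n_boundary_fits = n_boundary,
          k = sel$k, whitened = sel$whitened,
          moran_p = sel$moran$p.value,
          collinearity_groups = cgroups,
          n_candidates = length(cand),
          n_full_models = attr(cand, "n_full"),
          averaging = avg,
          best_model = paste(best$predictors, collapse = " + "),
          best_ols_r2_adj = best$ols_r2_adj))
        models[[key]] <- entry
      }
    }
  }

  manifest <- list(
    package = "phylogrid",
    version = as.character(utils::packageVersion("phylogrid")),
    seed = config$seed,
    stage_seeds = c(tree = child_seed(config$seed, 1L),
                    climate = child_seed(config$seed, 2L),
                    ranges = child_seed(config$seed, 3L),
                    nri_A = child_seed(config$seed, 4L),
                    nri_B = child_seed(config$seed, 5L)),
    config_hash = .config_hash(config),
    n_species = length(tree$tip.label),
    group_sizes = c(A = length(groups$A), B = length(groups$B)),
    n_cells = nrow(grid$pa),
    regions = {
      tb <- table(grid$cells$region)
      setNames(as.integer(tb), names(tb))
    })

  run <- structure(list(config = config, tree = tree, climate = climate,
                        grid = grid, groups = groups, metrics = metrics,
                        predictors = ptab, accessibility = accd,
                        forest_mask = mask, models = models,
                        cell_log = cell_log, manifest = manifest),
                   class = "phylogrid_run")
  say(sprintf("done in %.1f s", proc.time()[["elapsed"]] - t0))
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

# select_k with per-(cell set, k) eigen-decomposition reuse: the expensive
# part of a fit is the spectrum of W, shared across responses that use the
# same cells
.select_k_cached <- function(y, X, coords, config, wcache) {
  key0 <- paste(nrow(coords), paste(range(coords), collapse = ","),
                sum(coords), sep = "|")
  trace <- data.frame(k = integer(0), moran_i = numeric(0),
                      p.value = numeric(0))
  last <- NULL
  for (k in seq(config$k_start, config$k_min)) {
    key <- paste(key0, k)
    w <- wcache[[key]]
    if (is.null(w)) {
      w <- knn_weights(coords, k)
      wcache[[key]] <- w
    }
    fit <- fit_sar_error(y, X, w)
    mt <- morans_i(fit$residuals_filtered, w)
    trace <- rbind(trace, data.frame(k = k, moran_i = mt$statistic,
                                     p.value = mt$p.value))
    last <- list(k = k, fit = fit, weights = w, moran = mt,
                 whitened = !is.na(mt$p.value) && mt$p.value >= config$alpha,
                 trace = trace)
    if (last$whitened) return(last)
  }
  last$trace <- trace
  last
}

# stable hash of the configuration (md5 of its canonical deparse)
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config), control = "all"), f)
  unname(tools::md5sum(f))
}

#' Flatten a pipeline run into one result table
#'
#' One row per predictor of every successfully fitted group x region x
#' response model: the Akaike-averaged standardized coefficient, the
#' importance, and the model-level diagnostics (chosen k, residual Moran
#' p, best-model OLS adjusted R2).
#'
#' @param run a `phylogrid_run` from [run_all()].
#' @return data frame.
#' @export
results_table <- function(run) {
  stopifnot(inherits(run, "phylogrid_run"))
  rows <- lapply(run$models, function(m) {
    if (!identical(m$status, "ok")) {
      return(data.frame(group = m$group, region = m$region,
                        response = m$response, predictor = NA_character_,
                        coefficient = NA_real_, importance = NA_real_,
                        n_cells = m$n_cells, k = NA_integer_,
                        moran_p = NA_real_, best_ols_r2_adj = NA_real_,
                        status = m$status, stringsAsFactors = FALSE))
    }
    tab <- m$averaging$table
    data.frame(group = m$group, region = m$region, response = m$response,
               predictor = tab$predictor, coefficient = tab$coefficient,
               importance = tab$importance, n_cells = m$n_cells,
               k = m$k, moran_p = m$moran_p,
               best_ols_r2_adj = m$best_ols_r2_adj, status = "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.phylogrid_run <- function(x, ...) {
  cat("phylogrid pipeline run\n")
  cat(sprintf("  %d species (groups %d + %d), %d cells, seed %s\n",
              x$manifest$n_species, x$manifest$group_sizes[["A"]],
              x$manifest$group_sizes[["B"]], x$manifest$n_cells,
              format(x$manifest$seed)))
  ok <- sum(vapply(x$models, function(m) identical(m$status, "ok"), TRUE))
  cat(sprintf("  models: %d fitted, %d skipped\n", ok,
              length(x$models) - ok))
  invisible(x)
}
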