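#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study system: a birth-death phylogeny,
#' gradient-structured climate surfaces with a correlated Last Glacial Maximum
#' (LGM) counterpart, sub-cell elevation fields, and thermal-niche evolution
#' that places species on the grid. The defaults describe the study conditions
#' used throughout the package tests: a 20x20 grid of 100-km cells spanning a
#' 10 degC mean-annual-temperature gradient, 5 degC of LGM cooling, and
#' Brownian niche evolution fast enough to leave phylogenetic signal in
#' climate tolerances.
#'
#' @param n_tips number of extant species on the simulated tree (>= 2).
#' @param birth_rate,death_rate speciation and extinction rates per lineage
#'   per Myr; `death_rate` must be strictly smaller than `birth_rate`.
#' @param grid_rows,grid_cols grid dimensions (cells).
#' @param cell_size cell edge length in km.
#' @param gradient_strength mean-annual-temperature drop per grid row, degC.
#' @param noise_sd standard deviation of cell-level climate noise, degC
#'   (precipitation-type layers use scaled multiples of it).
#' @param lgm_offset LGM cooling applied to MAT, degC.
#' @param anomaly_amp amplitude of the smooth low-frequency LGM anomaly
#'   surface, degC; 0 makes the LGM field an exact shift of the present one.
#' @param niche_signal Brownian rate (degC^2 per Myr) of thermal-optimum
#'   evolution along the tree.
#' @param niche_noise standard deviation (degC) of a non-heritable deviation
#'   added to each species' optimum; 0 (default) gives pure Brownian optima.
#' @param niche_breadth thermal tolerance half-width, degC: a species occupies
#'   a cell iff |MAT - optimum| <= `niche_breadth`.
#' @param root_quantile quantile of the current MAT field used as the root
#'   (ancestral) thermal optimum; the warm-edge default 0.9 encodes a
#'   warm-origin flora in which cold tolerance is the derived state.
#' @param cold_clades number of cold-adapted clades (default 0). Each is a
#'   randomly chosen internal clade of `cold_clade_size` tips whose thermal
#'   optima are displaced toward the cold end of the gradient by a shared,
#'   inherited shift - the "cold tolerance evolved in few nested clades"
#'   structure of the tropical-niche-conservatism hypothesis.
#' @param cold_clade_size length-2 integer range of permissible clade sizes
#'   for the cold shifts.
#' @param cold_shift_frac displacement of a cold clade's optimum, as a
#'   fraction of the realized MAT span (default 0.65).
#' @param cold_clade_noise non-heritable optimum scatter (degC) for members
#'   of cold clades, replacing `niche_noise`; the smaller default models
#'   canalized cold specialists that co-occur as a group.
#' @param n_subcell number of sub-cell elevation samples per cell.
#' @param elev_roughness scale (m) of sub-cell elevation roughness.
#' @param max_retries bounded number of redraws when some species ends up
#'   with an empty range.
#' @param seed master integer seed; every `simulate_*` function derives its
#'   own deterministic child seed from it.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_phylogeny()], [simulate_climate()], [simulate_ranges()]
#' @export
#' @examples
#' cfg <- sim_config(n_tips = 20, grid_rows = 8, grid_cols = 8, seed = 42)
#' tr <- simulate_phylogeny(cfg)
sim_config <- function(n_tips = 100, birth_rate = 0.2, death_rate = 0.05,
                       grid_rows = 20, grid_cols = 20, cell_size = 100,
                       gradient_strength = 0.5, noise_sd = 0.5,
                       lgm_offset = 5, anomaly_amp = 1,
                       niche_signal = 1.5, niche_noise = 0,
                       niche_breadth = 3, root_quantile = 0.9,
                       cold_clades = 0, cold_clade_size = c(7, 10),
                       cold_shift_frac = 0.65, cold_clade_noise = 0.5,
                       n_subcell = 100, elev_roughness = 150,
                       max_retries = 100, seed = 1) {
  cfg <- list(n_tips = n_tips, birth_rate = birth_rate,
              death_rate = death_rate, grid_rows = grid_rows,
              grid_cols = grid_cols, cell_size = cell_size,
              gradient_strength = gradient_strength, noise_sd = noise_sd,
              lgm_offset = lgm_offset, anomaly_amp = anomaly_amp,
              niche_signal = niche_signal, niche_noise = niche_noise,
              niche_breadth = niche_breadth, root_quantile = root_quantile,
              cold_clades = cold_clades, cold_clade_size = cold_clade_size,
              cold_shift_frac = cold_shift_frac,
              cold_clade_noise = cold_clade_noise,
              n_subcell = n_subcell, elev_roughness = elev_roughness,
              max_retries = max_retries, seed = seed)
  counts <- c("n_tips", "grid_rows", "grid_cols", "n_subcell", "max_retries")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
      stop_("'", nm, "' must be a count >= 1")
    cfg[[nm]] <- as.integer(v)
  }
  nonneg <- c("birth_rate", "death_rate", "gradient_strength", "noise_sd",
              "anomaly_amp", "niche_signal", "niche_noise", "cell_size",
              "elev_roughness", "cold_clades", "cold_shift_frac",
              "cold_clade_noise")
  for (nm in nonneg) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_("'", nm, "' must be a non-negative number")
  }
  if (cfg$death_rate >= cfg$birth_rate)
    stop_("death_rate must be < birth_rate: the simulation is not ",
          "guaranteed to reach the requested number of tips otherwise")
  if (!(cfg$niche_breadth > 0))
    stop_("niche_breadth must be positive")
  if (cfg$root_quantile < 0 || cfg$root_quantile > 1)
    stop_("root_quantile must lie in [0, 1]")
  cfg$cold_clades <- as.integer(cfg$cold_clades)
  if (length(cfg$cold_clade_size) != 2L || any(cfg$cold_clade_size < 2) ||
      cfg$cold_clade_size[1L] > cfg$cold_clade_size[2L])
    stop_("cold_clade_size must be an increasing pair of counts >= 2")
  cfg$cold_clade_size <- as.integer(cfg$cold_clade_size)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed))
    stop_("seed must be a single finite number")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-study configuration\n")
  cat(sprintf("  tree : %d tips, birth %.3g, death %.3g /Myr\n",
              x$n_tips, x$birth_rate, x$death_rate))
  cat(sprintf("  grid : %d x %d cells of %g km\n",
              x$grid_rows, x$grid_cols, x$cell_size))
  cat(sprintf("  MAT  : gradient %g degC/row, noise sd %g, LGM offset %g\n",
              x$gradient_strength, x$noise_sd, x$lgm_offset))
  cat(sprintf("  niche: rate %g degC^2/Myr, breadth %g degC, root q%g\n",
              x$niche_signal, x$niche_breadth, x$root_quantile))
  cat(sprintf("  seed : %s\n", format(x$seed)))
  invisible(x)
}
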