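# phylogrid

Phylogenetic assemblage structure of gridded floras and its climatic
drivers.

Macroecologists mapping tree diversity on continental grids want to know
whether today's climate or the upheaval since the Last Glacial Maximum
(LGM, ~21,000 yr BP) shaped where lineages occur. `phylogrid` implements
that analysis end to end for cell-by-species presence grids with a dated
phylogeny:

* **Assemblage metrics** per grid cell — Faith's phylogenetic diversity
  `PD = Σ L_c` over the branches spanning the cell's species (root stem
  excluded), phylogenetic endemism `PE = Σ L_c / R_c` with each branch
  down-weighted by its range in cells, mean pairwise patristic distance
  (MPD), and the net relatedness index
  `NRI = −(MPD_obs − mean MPD_null) / sd MPD_null`, standardized against
  100 richness-matched random draws from the continental species pool
  (positive NRI = phylogenetic clustering).
* **Glacial-history predictors** — annual water balance `WBL = MAP − PET`;
  elevation heterogeneity (sub-cell sd); temperature-change velocity
  since the LGM (temporal change ÷ spatial gradient, km/yr); and
  postglacial accessibility `ACC = 1/(1 + D)`, where `D` is the
  multi-source least-cost distance from the glacial forest refugia
  through a cost graph whose edges are Euclidean distances in a
  three-component principal-component climate space.
* **Spatial inference** — maximum-likelihood SAR spatial-error
  regressions (`y = Xβ + u`, `u = λWu + ε`) on k-nearest-neighbour
  weights with k chosen by residual Moran's I (10 down to 4),
  collinearity-constrained candidate enumeration (`|r| > 0.5` groups),
  and Akaike-weight model averaging (ΔAIC < 10) with per-predictor
  importances, mirroring the standard multimodel-inference workflow.
* **A synthetic-data module** — birth–death phylogenies, gradient
  climate surfaces with LGM counterparts, niche-conserved species ranges
  (including rare clade-level cold-tolerance innovations), and
  SAR-structured responses — so the whole pipeline is testable without
  any external rasters.

## Worked example

A compact synthetic study — 40 species on a 15×15 grid of 100-km cells,
50 NRI randomizations — run through the full battery (2 clade groups ×
4 extents × 3 responses):

```r
library(phylogrid)

cfg <- run_config(
  sim = sim_config(n_tips = 40, grid_rows = 15, grid_cols = 15,
                   root_quantile = 0.5, niche_breadth = 4, seed = 11),
  n_null = 50, seed = 11)
run <- run_all(cfg, verbose = FALSE)
run
#> phylogrid pipeline run
#>   40 species (groups 22 + 18), 225 cells, seed 11
#>   models: 24 fitted, 0 skipped

run$models[["A.continental.pd"]]$averaging
#> Akaike model averaging: 16 of 39 models retained (dAIC < 10)
#>   predictor coefficient importance
#> 1       MAT      0.7367      0.927
#> 2        VT      0.0286      0.498
#> 3      EHET     -0.0034      0.179
#> 4       PRS     -0.0038      0.179
#> 5       WBL      0.0005      0.173
#> 6      TMIN      0.0575      0.073
#> 7       ACC      0.0000      0.000
#> 8       TES      0.0000      0.000
```

Reading the table: for the larger clade group's continental PD surface,
mean annual temperature dominates (Akaike importance 0.93, standardized
averaged coefficient +0.74 — warmer cells hold more branch length), the
glacial-instability predictors contribute little, and the temperature
collinearity group resolved mostly onto MAT rather than TMIN/TES/ACC.
`results_table(run)` flattens all 24 batteries into one data frame;
`run_all(cfg, outdir = "out")` additionally writes the tree (newick),
assemblage, metric, predictor and result tables plus a JSON manifest
with the seeds and configuration hash.

Individual stages are exported too: `compute_pd()`, `compute_pe()`,
`compute_nri()`, `temperature_velocity()`, `least_cost_accessibility()`,
`fit_sar_error()`, `model_average()`, `select_k()`, … — see the methods
vignette (`vignettes/phylogrid-methods.Rmd`) for the models, conventions
and design decisions.

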