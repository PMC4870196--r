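---
title: "Models and methods behind phylogrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylogrid}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phylogrid asks how current climate and glacial-interglacial climate change
shape the *phylogenetic* structure of species assemblages on a regular
macroecological grid. This vignette documents the statistical machinery —
the assemblage metrics, the paleoclimate predictors, the spatial regression
and multimodel averaging — and, because every piece is exercised on
synthetic data, the generative model behind that data, with the reasoning
for each design decision that was genuinely open.

## Assemblage metrics

For a grid cell holding species set $S$ on a dated phylogeny, the package
computes:

* **Phylogenetic diversity**, $PD = \sum_{c \in C} L_c$, the summed branch
  lengths $L_c$ (Myr) of the clade $C$ spanned by the minimal branch paths
  joining all of $S$. The spanning subtree is rooted at the most recent
  common ancestor of $S$ and **excludes** the branch subtending that
  ancestor. Cells with fewer than two species carry no PD value.
* **Phylogenetic endemism**, $PE = \sum_{c \in C} L_c / R_c$, where the
  range $R_c$ counts the grid cells whose spanning set contains branch $c$.
  PE concentrates branch length on geographically restricted lineages and
  is `log(PE + 1)`-transformed for modelling because its surface is
  strongly right-skewed.
* **Mean pairwise distance** (MPD): the mean patristic distance over all
  unordered species pairs in the cell. On an ultrametric tree the patristic
  distance is twice the pair's divergence time; the z-score below is
  invariant to that factor of two.
* **Net relatedness index**,
  $NRI = -( MPD_{obs} - \overline{MPD}_{null} ) / sd(MPD_{null})$,
  with the null built from 100 uniform without-replacement draws of the
  cell's richness from the continental species pool. Positive NRI means
  the assemblage is more closely related than random — phylogenetic
  clustering.

Three conventions deserve comment because published implementations differ:

* **One clade definition for PD, PE and $R_c$.** Because both metrics share
  the clade $C$, the MRCA-rooted, stem-excluded subtree is used for all
  three computations. This preserves an exact conservation identity —
  summed over all cells, PE equals the total length of every branch spanned
  anywhere — which the test suite checks to $10^{-9}$ relative error.
  Rosauer's original endemism code instead follows branches down to the
  tree root; that variant is available everywhere via `include_root = TRUE`
  (the identity then holds under the same flag for $R_c$).
* **Null standardization.** The pool is the full species group present
  anywhere on the grid, also for regional models, mirroring a single
  continental standardization; draws are unweighted and without
  replacement; the null standard deviation uses the $n-1$ denominator.
  Degenerate nulls (e.g. richness equal to the pool) yield missing values
  and a message rather than an infinity.
* **Species absent from the tree are a hard error**, not a silent drop:
  on real data those species must be grafted or removed deliberately.

## Paleoclimate predictors

Eight per-cell predictors enter the models: MAT, TMIN, TES, PRS
(pass-through climate layers), annual water balance
$WBL = MAP - PET$ (mm), elevation heterogeneity EHET (the standard
deviation of sub-cell elevation samples; square-root-transformed),
temperature-change velocity VT (log-transformed) and postglacial
accessibility ACC (log-transformed).

**Velocity.** VT is the temporal MAT change since the Last Glacial Maximum
(default 21,000 yr) divided by the local spatial MAT gradient, in km/yr —
the migration rate needed to track an isocline. The gradient comes from
3x3 central differences (one-sided on the boundary) and is floored at
$10^{-4}$ degC/km so flat terrain produces large finite velocities rather
than a division by zero. The ratio is oriented as temporal/spatial;
the inverse would carry yr/km and could not be read as a migration rate.

**Accessibility.** Cells are nodes of a graph connecting grid neighbours
(queen moves by default; rook available), each edge weighted by the
Euclidean distance between the two cells' scores on the first three
principal components of 19 standardized bioclim-like layers. The PCA uses
the correlation matrix, appropriate for variables of heterogeneous units,
with signs fixed so each component's largest loading is positive. From
every LGM forest source cell, multi-source Dijkstra accumulates the least
climatic cost $D$, and $ACC = 1/(D+1) \in [0, 1]$: 1 on in-situ glacial
forest, 0 at infinite cost. No geometric diagonal correction is applied to
queen edges — the costs are purely climatic, not geometric. The glacial
forest mask itself is pluggable: a climate-envelope rule over the LGM
layers or any user-supplied binary mask (hindcast species-distribution
modelling is deliberately out of scope).

**Transforms.** ACC and VT are natural-log transformed; exact zeros are
replaced by a configurable positive offset (default half the smallest
positive value) that is recorded in the table's metadata.

## Spatial regression and multimodel inference

Responses (PD, NRI, log1p-PE) are related to predictors with
simultaneous autoregressive **spatial-error** models,
$y = X\beta + u,\; u = \lambda W u + \varepsilon$, fitted by maximum
likelihood. $W$ is a row-standardized k-nearest-neighbour weight matrix;
for each candidate $\lambda$ the spatially filtered regression
$(I-\lambda W) y \sim (I-\lambda W) X$ profiles out $\beta$ and
$\sigma^2$, and the concentrated likelihood — with
$\log|I - \lambda W|$ evaluated from the (possibly complex) spectrum of
$W$, computed once per weight matrix and cached — is maximized over
$(-0.999, 0.999)$. Fixing $\lambda = 0$ reproduces ordinary least squares
exactly, which anchors the unit tests. A profile that is monotone up to the
constraint is reported as a boundary fit with a warning and its likelihood
bracket; the response and predictors are z-standardized by default so
coefficients are standardized effect sizes.

Model selection follows the multimodel-averaging recipe:

1. **Collinearity groups**: predictors joined by $|r| > 0.5$ edges form
   connected components; one member per group may enter a model. With the
   reference correlation structure this yields the groups
   {MAT, TMIN, TES, ACC} and {VT, EHET}, WBL and PRS free — hence
   $4 \times 2 = 8$ full models and 59 distinct candidate models after
   deduplicating the nested subsets shared between full-model lattices
   (each distinct subset is fitted once).
2. **AIC averaging**: models within $\Delta AIC < 10$ of the best are
   retained and Akaike-weighted; averaged coefficients use zero
   substitution (an absent predictor contributes 0), so coefficients and
   importances — the summed weights of models containing a predictor —
   share one weight base. Conditional averaging is available by flag. AIC
   counts the regression coefficients (including the intercept) plus
   $\lambda$ and $\sigma^2$; only differences matter for selection, and
   the convention is recorded in every fit object.
3. **k selection**: k walks down from 10 to 4 until Moran's I of the
   *spatially filtered* residuals $\hat\varepsilon = (I - \hat\lambda W)
   (y - X\hat\beta)$ is non-significant (normality variance, two-sided);
   if no k passes, k = 4 is used and flagged. The filtered residuals are
   the whitened innovations of the model — the raw residuals $y - X\beta$
   retain the modelled autocorrelation whenever $\lambda > 0$ and would
   force the fallback k on every well-fitted spatial model.
4. A companion OLS adjusted $R^2$ accompanies every fit, reported for the
   best model of each battery entry.

## The synthetic study system

No external rasters or atlases are required: the generator produces each
input with the statistical structure the analysis assumes.

* **Phylogeny**: a crown birth-death process simulated forward until the
  number of coeval lineages first reaches `n_tips`, then extended by one
  exponential waiting time so no pendant branch has zero length; extinct
  lineages are pruned. Under pure birth the expected crown depth is
  $(H_n - 1)/b$, the closed form the test suite uses as an oracle.
* **Climate**: MAT falls linearly along rows (latitude) with Gaussian
  cell noise; TMIN, TES, MAP, PET and PRS are correlated derivatives; the
  LGM counterpart subtracts a uniform cooling plus a smooth low-frequency
  anomaly surface so velocity varies in space; 19 bioclim-like layers are
  random mixtures of the four base gradients; sub-cell elevation combines
  a base ramp with two-octave roughness that grows eastward, giving EHET
  spatial structure.
* **Ranges**: each species' thermal optimum evolves by Brownian motion
  (rate `niche_signal`, degC$^2$/Myr) from an ancestral state at a chosen
  MAT quantile, optionally blurred by a non-heritable `niche_noise`; a
  species occupies cells within `niche_breadth` of its optimum. A species
  whose optimum leaves it with an empty range has its terminal-branch
  deviation redrawn (bounded retries with a slowly inflating scale, then
  a uniform draw over the feasible interval) so no species is silently
  dropped. Pure Brownian motion has scale-invariant phylogenetic signal,
  so the signal-monotonicity property is only meaningful against a fixed
  `niche_noise` floor; the test fixes it at 0.5 degC.
* **Cold-clade innovations.** Development showed that Brownian optima
  alone do *not* reliably produce the niche-conservatism signature
  (clustering toward cold): the cold tail of a Brownian trait is as often
  a set of convergent excursions by unrelated lineages as a clade, and a
  richness-matched full-pool null gives any species-rich cell that lacks
  a deep clade a positive NRI bias growing with $\sqrt{richness}$. The
  generator therefore offers clade-level cold-tolerance innovations:
  `cold_clades` disjoint internal clades (never an entire root side)
  inherit a large cold-ward optimum shift, with the tight scatter of
  canalized specialists. This encodes the hypothesis directly — cold
  tolerance as a rare, inherited innovation in an ancestrally warm flora —
  and yields the directional NRI-temperature pattern robustly. The frozen
  strong-conservatism condition used by the directional test: 150 species,
  20x20 grid, 10 degC gradient, non-heritable scatter 1.2 degC, breadth
  1.5 degC, ancestral optimum at the 0.9 MAT quantile, one cold clade of
  7-10 species shifted 65% of the span, and the Spearman correlation is
  taken over cells with at least five species, the same richness filter
  the modelling stage applies. Defaults keep `cold_clades = 0` (pure
  Brownian behaviour).
* **SAR responses**: `simulate_sar_response()` draws
  $y = X\beta + (I - \lambda W)^{-1}\varepsilon$ for parameter-recovery
  experiments.

What the generator does **not** emulate: real geography and coastlines,
range cohesion (ranges are climate bands, not spreading processes),
observation error in occurrences, and climate-niche dimensions beyond
temperature. Passing tests therefore demonstrate that the *machinery*
recovers known structure under its assumptions, not that those assumptions
hold for any particular flora.

## The orchestrated run

`run_all()` composes the stages for two species groups — the two most
balanced complementary clades of the simulated tree, the
angiosperm/gymnosperm analog; a pure root split is often so unbalanced
that one group would be unanalyzable — across the continental extent and
three latitude-band regions (north; the southern remainder split at the
median longitude into west and east). Cells must hold at least 5 species
of the larger group (2 for the smaller) to enter a model, metrics are
computed before filtering (maps cover more cells than models use), every
excluded cell carries a reason code, and all randomness derives from one
master seed through fixed per-stage offsets, so a rerun reproduces every
table and the manifest exactly. A predictor that is constant within one
model's cell subset (e.g. ACC in an all-refugium region) is dropped from
that model and recorded.

The reference configuration (`run_config()` defaults) uses 60 species on
a 30x30 grid of 100-km cells, a mid-gradient ancestral optimum and 4 degC
tolerance — conditions under which both groups span all regions and the
full 2 groups x 4 extents x 3 responses battery is estimable — with 100
NRI randomizations per cell. It completes in well under a minute on one
CPU; the test suite's property checks use the problem sizes stated in
each test (up to 945 six-tip topologies, 100-seed recovery experiments at
n = 400, and 100-seed directional tests on the 20x20 grid).

## Numerical choices and limitations

* kNN distance ties break by cell index; duplicate coordinates are
  rejected by the SAR fit only implicitly (they produce aliased weights),
  so gridded centroids should be unique.
* The eigenvalue log-determinant is exact for the dense weight matrices
  used here (n up to a few thousand); no sparse approximation is shipped.
* Moran's I uses the normality variance; a randomization variance is not
  implemented.
* NRI draws its null per cell; two cells of equal richness receive
  independent draws under one seed, and surfaces are reproducible only
  through the `seed` argument.
* PE for a single-species cell is 0 under the MRCA convention (its
  spanning set is empty); such cells are excluded from modelling by the
  richness filters anyway.
* The collinearity threshold (0.5), AIC window (10), k range (10 down to
  4) and richness filters (5 and 2) are the analysis constants of the
  reference design; all are arguments, none is hard-coded.
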