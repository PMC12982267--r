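---
title: "Methods: species-based urban pollinator connectivity"
author: "pollinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-based urban pollinator connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`pollinet` implements a species-based workflow for mapping where insect
pollinators can move through an urban landscape, and for comparing the
result against an independently drawn corridor network. The chain is:

1. clean citizen-science-style occurrence records and draw biased
   background points;
2. fit a penalized additive logistic habitat-suitability model per species
   on focal land-cover predictors;
3. combine the per-species maps, invert the combined surface into a
   movement resistance, and delineate core habitat areas;
4. model movement as a random walk on the resistance lattice (circuit
   theory), yielding per-cell current and pairwise effective resistances;
5. extract least-cost corridors between the most suitable ("critical")
   cores and the pinch points within them;
6. overlay the species-based corridors on a planner corridor network and
   quantify agreement with independent records.

Because the real inputs of such a study (municipal biological records,
national land-cover products, planner corridor layers) cannot be bundled,
the package includes a first-class synthetic-data module with known ground
truth. Every stage is therefore testable end to end: filtering is checked
against an exact contamination ledger, model fitting against the generating
suitability function, and the solvers against closed forms and dense linear
algebra.

# The synthetic study system

`synthetic_scenario()` fixes the study conditions; `generate_landscape()`,
`true_suitability()`, `bias_surface()` and `generate_occurrences()` are
deterministic functions of it. All randomness flows from one integer seed
through `split_seed()`, so stages are independently reproducible.

**Landscape.** Seven land-cover classes (woodland, wetland, arable,
grassland, garden, allotment, impervious) are laid down at 10 m resolution:
each class gets a latent Gaussian random field (FFT-smoothed white noise,
Gaussian kernel), and a cell takes the class whose offset field is largest,
with offsets calibrated by fixed-point iteration so that realised class
fractions track the target composition (defaults roughly echo a UK city:
25% impervious, 22% grassland, 15% each woodland and gardens). The field
correlation length defaults to 200 m, a grain that produces a patchy urban
mosaic — tens of distinct habitat patches over the 6.4 km demo extent —
rather than one monolithic blob; elevation and population-density surfaces
come from further fields, population partially tied to the impervious
field, mimicking the built-up/population correlation of real cities.

**Ground truth and records.** Each species has a known additive suitability
function on the raw focal predictors (e.g. the bumblebee-like species rises
with grassland and garden cover, peaks at intermediate woodland, and
declines with impervious cover). Presences are drawn cell-wise with
probability proportional to suitability times an observer-effort surface (a
Gaussian-kernel "city centre" bias, strength 0 disables it). Dates are
year-resolution, uniform on 2015–2022. Contamination — exact duplicates,
records with > 100 m coordinate uncertainty, undated records, out-of-window
years — is injected in known counts and booked in a ledger; the filter
audit must reproduce it exactly, which the tests assert.

What the generator does **not** emulate: taxonomic misidentification,
spatially varying detectability conditional on effort, multi-year landscape
change, and real Scottish land-cover typology. Passing tests demonstrate
the pipeline's internal correctness and recoverability under known truth —
not that any particular real-world dataset would yield the same ecology.

# Record handling

`filter_records()` applies the rules in a fixed order (out-of-window year,
then uncertainty, then undated, then duplicates on species/x/y/year), so
every removal is counted under exactly one reason and filtering is
idempotent. Missing uncertainty fails the 100 m rule — the conservative
reading. `kde_background()` draws, per species, ten times the presence
count from the valid analysis cells with probability proportional to a
Gaussian KDE of that species' presences (Silverman's rule per axis by
default). Sampling is with replacement so that the empirical background
density stays proportional to the KDE; distinct-cell sampling is available
(`replace = FALSE`) for workflows that want at most one point per cell.
`assemble_model_frame()` weights presences by `n_background / n_presence`
(then rescales to mean 1) so both classes carry equal total weight.

# Predictors

`focal_proportion()` and `focal_mean()` summarise the fine rasters over a
100 m-radius disc centred on each analysis-cell centre; a fine cell belongs
to the disc when its centre lies within the radius (centre cell included).
A disc rather than a square window was chosen as the more common reading of
"within 100 m"; the focal tests enumerate the disc brute-force, so the
membership rule is pinned down exactly. Altitude is square-root transformed
*after* averaging; all layers are z-scored with the sample (n−1) standard
deviation and the constants are stored so points and prediction grids share
one scale. `correlation_screen()` computes Spearman correlations at the
model points, groups layers transitively at |rho| > 0.7, and keeps the
layer ranked first in a total preference order; the default order puts
gardens ahead of impervious cover and population density — gardens being
the directly manageable, resource-bearing quantity of the three.

# The suitability model

Each species gets a binomial (logit) additive model:

- **Univariate smooths.** Cubic B-splines of rank 5 (interior knot at the
  median) with a second-order coefficient-difference penalty (P-splines),
  capping each term at 4 effective degrees of freedom. The penalty null
  space (constant + linear in the basis index) carries a separate identity
  penalty — the double-penalty construction — so a term can be shrunk
  completely out of the model, which is how predictor selection happens.
- **Spatial term.** A Gaussian radial basis over (x, y) with ~30 k-means
  centres and a ridge penalty, absorbing residual spatial autocorrelation.
- **Fitting.** Penalized weighted IRLS with step-halving; the penalized
  deviance is non-increasing by construction (asserted in tests).
  Divergence (|coefficient| > 1e4) is reported as likely complete
  separation.
- **Smoothing selection.** Coordinate descent over a log-spaced grid
  (1e-3 … 1e6) per penalty, scored by the unpenalized weighted deviance on
  an internal stratified 75/25 hold-out plus a `log(n)`-weighted effective-df
  penalty; among candidates within a small slack of the optimum the
  strongest smoothing wins. The complexity penalty matters: under pure
  noise the hold-out deviance profile is flat to within sampling noise, and
  without it the selected smoothing is arbitrary; with it, null terms
  collapse to zero effective df while real structure — whose deviance gains
  dwarf `log(n)` per df — keeps its wiggle room. This grid search is a
  deliberately simple surrogate for restricted-maximum-likelihood
  smoothing selection; the package validates itself by parameter recovery
  (correlation with the true linear predictor > 0.9 at n = 2000) rather
  than coefficient-level equality with any particular GAM implementation,
  and an unpenalized fit on the same basis is cross-checked against `glm`.
- **Reporting.** Effective df per term is the trace of the corresponding
  hat-matrix block; terms below 0.1 edf are reported "shrunk out" (an
  operational threshold, not a significance test).

Per-species maps are inverse-logit evaluations over the standardised stack
(spatial term included), summed, and min–max rescaled to [0, 1]; min–max
was chosen over division by the species count because it fixes both ends
of the scale that downstream thresholds (0.5, 0.9) refer to, and it makes
the combination invariant to adding a constant to any one map. Pearson
correlations of the combined map with each input are reported so the user
can check that species-specific structure survives.

# Evaluation

`make_folds()` supports uniform k-fold, spatially blocked k-fold (whole
blocks of `block_size_m` allocated to folds; 5 km by default, 800 m in the
demo so that more than k blocks exist at a 6.4 km extent), and a repeated
stratified 75/25 split mode. The k-fold and split modes are both provided
because a "10-fold CV allocating 75% and 25%" protocol is internally tense
(10-fold implies 90/10); the package defaults to k-fold and leaves the
choice to the user. AUC is the rank-statistic formulation (ties count
half). The continuous Boyce index uses 101 overlapping windows of width
0.1 over [0, 1] — standard defaults — skipping windows with zero expected
fraction, and is the Spearman correlation of P/E with the window midpoint.
`tss_curve()` sweeps all unique scores plus a 0.01 grid; maxSSS maximises
sensitivity + specificity and MDT minimises their gap, ties resolving to
the smaller threshold. Cross-validation refits coefficients per fold at
the smoothing parameters selected on the full data (re-selecting per fold
would be slower and noisier), and reports mean ± sd per metric; the final
coefficients always come from the all-data fit.

# Connectivity

Resistance is `1 / max(s, 1e-3)` — the multiplicative-inverse reading of
"inverse suitability", floored so fully unsuitable cells stay finite;
`1 − s` is available as a configuration alternative. Core areas are
groups of ≥ 2 cells with combined suitability ≥ 0.5 under queen (8-neighbour)
adjacency; groups farther than 300 m from every other group are dropped by
default (the isolation-filter reading of the linkage rule), with a merge
mode available since the rule could also be read as joining nearby groups
into one node. The lattice graph joins neighbouring cells with conductance
`1 / (d · (r_i + r_j)/2)`, `d` = 1 or √2 in cell units — the mean-resistance
edge rule, one of the standard discretisations. For a pair solve the cells
of each core are collapsed into supernodes, the target is grounded, and the
sparse Laplacian system is solved; per-cell current is half the sum of
absolute incident edge currents, and effective resistance is the
source-target voltage per unit injection. The solver is verified against a
dense Laplacian-pseudoinverse oracle (1e-8), closed-form series circuits
(1e-12), Kirchhoff balance at 1e-9, and resistance-scaling invariance.
Cumulative current sums all unordered core pairs, excluding each pair's own
core cells; when there are very many cores the pipeline solves the largest
25 (configurable) — pair count grows quadratically and the large cores
dominate the map.

# Corridors and pinch points

Cost-weighted distance from a core is Dijkstra over the same lattice with
edge cost `d · (r_i + r_j)/2 · cell size`; the corridor between cores A and
B is the set of cells whose `cwd_A + cwd_B` lies within a cutoff of the
least-cost-path cost. No cutoff is canonical, so the default is five
average cell-crossing costs (5 × mean resistance × cell size), exposed as a
parameter. Current is then re-solved with the surface masked to the
corridor, the top 1% of corridor current is thresholded per pair, and cells
are merged across pairs before clustering (≥ 2 neighbouring cells), giving
one merged pinch-point map. Critical cores use the 0.9 threshold with the
same ≥ 2-cell rule and no isolation filter — at 0.9 the surviving patches
are few and dropping isolated ones would frequently leave nothing to
connect.

# Corridor comparison

The species corridor mask is the top 10% of cumulative current (ties at
the threshold included). Planner polygons are rasterised by cell-centre
coverage — bit-exact and easy to oracle-check — and every valid cell is
labelled both / species-only / planner-only / neither. Relative
probability per category divides the fraction of independent presences by
the fraction of 20,000 uniform background points; uniform rather than
KDE-weighted because this stage is validation, not modelling. Pinch
clusters count as overlapping the planner network if any member cell
centre falls inside a polygon, attributing the whole cluster — matching
cluster-count reporting. Under a uniform-presence null all four ratios sit
within 10% of 1 at these sample sizes, which the tests assert over ten
seeds.

# Numerical choices and degenerate inputs

- ESRI ASCII (.asc) is the raster interchange format: plain text, readable
  by GDAL/QGIS/ArcGIS, round-trip exact at the precisions used here.
  Polygons travel as GeoJSON; land-cover class names are stored alongside
  since .asc carries only codes.
- Quantile thresholds (top 1%, top 10%) use R's default type-7 quantile;
  ties at the threshold are included. An all-constant raster yields a
  degenerate percentile and zero pinch clusters (warning), but a full
  top-fraction mask (every cell ties at the threshold) — both behaviours
  documented rather than silently chosen.
- The IRLS normal equations carry a 1e-8 ridge for numerical safety;
  smooth bases clamp out-of-range values (constant extrapolation).
- Empty planner layers, unreachable core pairs (infinite effective
  resistance), single-class CV folds (skipped with a warning) and empty
  corridor masks are all handled without crashing and flagged in output.

# Problem sizes

The bundled demo runs a 64 × 64 analysis grid (640 × 640 fine cells), three
species with 150 clean presences each, 10-fold CV in both modes, all-pairs
circuit solves, and the full comparison stage — about half a minute on one
CPU. The verification suites use 100 random grids up to 20 × 20 for the
dense-oracle check, 50 random 4 × 4 grids for exhaustive path enumeration,
and 20 recovery replicates at n = 2000. These sizes were chosen so the
whole battery runs comfortably on a laptop while keeping every check
non-trivial.

# Known limitations

- The smoothing-parameter search is a hold-out grid approximation, not
  REML; fits will differ in detail from `mgcv` even on identical data.
- Effective-df "shrunk out" reporting is an operational convention, not an
  inferential test; no p-values are produced.
- The corridor cutoff and the 4/8-neighbour choice are not dictated by any
  authority; defaults are documented and configurable, and queen adjacency
  with √2 diagonals is used throughout for consistency.
- All inputs must share one projected planar CRS in metres; there is no
  reprojection.
- The planner-corridor generator is a geometric stand-in (buffered
  minimum-spanning-tree links between qualifying patches), not a
  re-implementation of any planning authority's workflow; it exists so the
  comparison stage has a realistic, independently constructed input.
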