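# pollinet

Species-based urban connectivity modelling for insect pollinators, as a
tested R package plus a numbered analysis workflow.

## The problem

Urban planners increasingly design "nature networks" — corridors and
stepping stones meant to let pollinators move between fragmented habitat
patches. Two families of methods are used to draw such corridors: expert /
least-cost approaches working from habitat maps, and species-based
approaches that model habitat suitability from occurrence records and then
compute connectivity over the resulting surface. `pollinet` implements the
second, species-based chain end to end and the machinery to compare its
corridors against an independently supplied planner network:

1. **Records** — filter biological records (year window 2015–2022, ≤ 100 m
   coordinate uncertainty, dated, de-duplicated; every removal audited) and
   draw background (pseudo-absence) points at 10× the presence count,
   weighted by a kernel density of the presences to absorb recording bias.
2. **Predictors** — focal proportions of land-cover classes (woodland,
   wetland, arable, grassland, gardens, allotments, impervious) within a
   100 m radius, plus √(mean altitude) and mean population density; z-scored;
   Spearman |ρ| > 0.7 collinearity screen with gardens preferred.
3. **Suitability** — per species, a binomial (logit) additive model with
   cubic-spline smooths capped at 4 effective df, a low-rank spatial smooth
   in (x, y), equal total weight on presences and background, and
   double-penalty shrinkage so uninformative terms are removed by the data:

   logit P(presence) = β₀ + Σⱼ fⱼ(xⱼ) + f_xy(x, y),
   fitted by penalized IRLS maximising the weighted log-likelihood minus
   Σⱼ (λⱼ θᵀSⱼθ + λ*ⱼ θᵀUⱼθ).

   Validated by random and spatially blocked 10-fold cross-validation with
   AUC, the continuous Boyce index, and TSS at the maxSSS threshold.
4. **Connectivity** — per-species maps summed and min–max normalised;
   resistance r = 1/max(s, ε); core areas = groups of ≥ 2 adjacent cells
   with s ≥ 0.5 within 300 m of another group; movement modelled as current
   flow on the conductance lattice (graph-Laplacian solves with cores
   collapsed to supernodes), giving a cumulative current map and pairwise
   effective resistances.
5. **Pinch points** — least-cost corridors between critical cores
   (s > 0.9), circuit solves restricted to each corridor, clusters of ≥ 2
   neighbouring cells in the top 1% of current.
6. **Comparison** — the top 10% of current versus planner corridor
   polygons: four-category gap areas (both / species-only / planner-only /
   neither), relative probability of independent records per category
   against 20,000 uniform background points, land-cover and
   distance-to-centre descriptives, and pinch-cluster overlap counts.

Real inputs of this kind (municipal records, national land-cover rasters,
planner corridor layers) are not redistributable, so the package ships a
synthetic-data module with known ground truth: autocorrelated multi-class
landscapes, species with known additive suitability functions, observer
bias, record contamination with an exact ledger, and planner-style corridor
polygons. Every downstream stage is tested against that truth or against
independent brute-force oracles (dense Laplacian pseudoinverse, exhaustive
path enumeration, flood fill, full sorts).

## Worked example

```r
library(pollinet)
cfg <- demo_config(seed = 1)          # 6.4 km x 6.4 km, 3 species
cfg$out_dir <- "pollinet-output"
res <- run_pipeline(cfg)
```

prints, among other stage logs (about half a minute on one CPU):

```
[3/9] filtering records
      522 -> 450 records (removed 12 year, 24 uncertainty, 12 undated, 24 duplicate)
[6/9] per-species models + cross-validation
      bombus: AUC 0.68 (random) / 0.69 (spatial); edf: wood 2.8, wet 1.2, ...
[7/9] combined map, resistance, cores, circuit solve
      3 core areas, 23.65 km^2 (57.7% of the study area)
[8/9] pinch-point analysis (tau > 0.9)
      20 pinch clusters, 8.290 km^2
[9/9] planner corridors + gap analysis
      overlap 3.58 km^2; pinch clusters 20 in / 0 out of planner corridors
```

The filter line closes the loop on the generator's contamination ledger
(12 + 24 + 12 + 24 injected bad records, all caught under the right
reason). The per-species lines report cross-validated discrimination and
which predictors survived shrinkage; the later stages report the core-area
extent, the pinch-point clusters, and the gap analysis against the
synthetic planner network. All artefacts (rasters as ESRI ASCII, polygons
as GeoJSON, records as CSV, a JSON report) are written to `out_dir`,
stamped with the seed and a configuration fingerprint; the same
config + seed reproduces them byte for byte.

The same pipeline is also broken out as a narrated workflow in
`analysis/01_simulate.R` … `analysis/08_compare.R`, each stage reading the
previous stage's files and writing its tables under `results/demo/`.
`vignettes/pollinator-connectivity-methods.Rmd` documents the model, the
parameter choices and their defaults, the synthetic study system, and known
limitations.

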