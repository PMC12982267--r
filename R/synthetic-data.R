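#' Derive a stream seed from the scenario master seed
#'
#' All randomness in the synthetic-data module flows from one integer seed;
#' independent stages draw from deterministic sub-seeds so that adding a new
#' stage does not perturb earlier ones.
#'
#' @param seed master integer seed.
#' @param stream small integer stream index.
#' @return an integer seed < 2^31.
#' @export
split_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 2654435) %% 2147483647)
}

#' Land-cover classes used by the synthetic landscapes
#' @export
LANDCOVER_CLASSES <- c("woodland", "wetland", "arable", "grassland",
                       "garden", "allotment", "impervious")

#' Define a synthetic study scenario
#'
#' A scenario fixes everything the generator needs: landscape geometry and
#' composition, spatial autocorrelation, per-species ground-truth suitability
#' functions, sampling effort, observer bias and record contamination rates.
#' The scenario is the single source of truth for a simulated study; all
#' downstream stages are deterministic functions of it.
#'
#' @param seed master integer seed.
#' @param extent c(width, height) of the landscape in metres.
#' @param fine_res land-cover cell size (m); must divide `analysis_res`.
#' @param analysis_res analysis grid cell size (m).
#' @param class_weights named target fractions over `LANDCOVER_CLASSES`
#'   (must sum to 1).
#' @param smoothness correlation length of the latent Gaussian fields (m).
#' @param n_presence_per_species clean presence records per species.
#' @param bias_strength observer-bias intensity (>= 0; 0 = unbiased).
#' @param contamination named fractions (of the clean presence count) of
#'   injected bad records: `duplicates`, `uncertain`, `undated`, `out_year`.
#' @param years inclusive year range of the study window.
#' @param true_coefficients named list (per species) with elements
#'   `intercept` (numeric) and `effects` (named list of functions of the raw
#'   predictor value, returning a contribution to the linear predictor).
#' @return object of class `SyntheticScenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               extent = c(6400, 6400),
                               fine_res = 10,
                               analysis_res = 100,
                               class_weights = c(woodland = 0.15, wetland = 0.08,
                                                 arable = 0.10, grassland = 0.22,
                                                 garden = 0.15, allotment = 0.05,
                                                 impervious = 0.25),
                               smoothness = 200,
                               n_presence_per_species = 150,
                               bias_strength = 1,
                               contamination = c(duplicates = 0.05, uncertain = 0.05,
                                                 undated = 0.03, out_year = 0.03),
                               years = c(2015L, 2022L),
                               true_coefficients = default_true_coefficients()) {
  if (any(extent <= 0) || fine_res <= 0 || analysis_res <= 0)
    stop("extent and resolutions must be positive")
  if (abs(analysis_res / fine_res - round(analysis_res / fine_res)) > 1e-9)
    stop("fine_res must divide analysis_res")
  if (abs(sum(class_weights) - 1) > 1e-9)
    stop("class_weights must sum to 1")
  if (any(class_weights < 0) || any(class_weights > 1))
    stop("class_weights must lie in [0, 1]")
  miss <- setdiff(names(class_weights), LANDCOVER_CLASSES)
  if (length(miss)) stop("unknown land-cover classes: ", paste(miss, collapse = ", "))
  cont <- c(duplicates = 0, uncertain = 0, undated = 0, out_year = 0)
  cont[names(contamination)] <- contamination
  if (any(cont < 0) || any(cont > 1)) stop("contamination fractions must be in [0, 1]")
  if (bias_strength < 0) stop("bias_strength must be >= 0")
  structure(
    list(seed = as.integer(seed), extent = extent, fine_res = fine_res,
         analysis_res = analysis_res, class_weights = class_weights,
         smoothness = smoothness,
         n_presence_per_species = n_presence_per_species,
         bias_strength = bias_strength, contamination = cont,
         years = as.integer(years), true_coefficients = true_coefficients),
    class = "SyntheticScenario"
  )
}

#' Default ground-truth suitability coefficients for three pollinator-like species
#'
#' Three generalist species with contrasting additive responses to the focal
#' land-cover predictors: a bumblebee-like species favouring gardens and
#' grassland, a woodland-edge butterfly, and a dry-grassland butterfly
#' avoiding impervious cover. Effects act on raw (unstandardised) focal
#' proportions, sqrt-altitude and population density.
#'
#' @return named list suitable for `synthetic_scenario(true_coefficients=)`.
#' @export
default_true_coefficients <- function() {
  list(
    bombus = list(
      intercept = -2.0,
      effects = list(
        grass  = function(v) 3.0 * v,
        garden = function(v) 2.5 * v,
        wood   = function(v) 2.0 * v - 3.5 * v^2,
        imperv = function(v) -2.0 * v
      )
    ),
    ringlet = list(
      intercept = -2.2,
      effects = list(
        wood  = function(v) 3.5 * v - 2.0 * v^2,
        wet   = function(v) 2.0 * v,
        alt   = function(v) 0.15 * v,
        grass = function(v) 1.5 * v
      )
    ),
    small_heath = list(
      intercept = -1.8,
      effects = list(
        grass  = function(v) 3.5 * v,
        arable = function(v) 1.0 * v,
        imperv = function(v) -3.0 * v,
        popdensity = function(v) -0.02 * v
      )
    )
  )
}

# Stationary Gaussian random field on a grid via circulant (FFT) embedding of
# a Gaussian smoothing kernel; periodic boundary, standardised to mean 0 sd 1.
gaussian_field <- function(nr, nc, range_cells, seed) {
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells <= 0) return((z - mean(z)) / stats::sd(z))
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- outer(exp(-di^2 / (2 * range_cells^2)), exp(-dj^2 / (2 * range_cells^2)))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

#' Generate the synthetic landscape rasters
#'
#' Builds a categorical land-cover raster at the fine resolution plus
#' continuous elevation and human-population-density rasters. Each land-cover
#' class gets its own latent Gaussian random field (correlation length
#' `scenario$smoothness`); a cell takes the class whose offset field is
#' largest, with the per-class offsets calibrated by fixed-point iteration so
#' empirical class fractions track `class_weights`.
#'
#' @param scenario a `SyntheticScenario`.
#' @return list with `landcover` (codes indexing `levels` attribute of the
#'   returned grid's `$levels`), `elevation` (m, >= 0) and `population`
#'   (people/ha, >= 0), all `RasterGrid`s at `fine_res`.
#' @export
generate_landscape <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  nr <- as.integer(round(scenario$extent[2] / scenario$fine_res))
  nc <- as.integer(round(scenario$extent[1] / scenario$fine_res))
  rng <- scenario$smoothness / scenario$fine_res
  active <- names(scenario$class_weights)[scenario$class_weights > 0]
  w <- scenario$class_weights[active]

  fields <- lapply(seq_along(active), function(k)
    gaussian_field(nr, nc, rng, split_seed(scenario$seed, 100 + k)))

  if (length(active) == 1L) {
    cls <- matrix(1L, nr, nc)
  } else {
    delta <- rep(0, length(active))
    flat <- vapply(fields, as.vector, numeric(nr * nc))
    for (it in 1:200) {
      assign <- max.col(sweep(flat, 2, delta, "+"), ties.method = "first")
      frac <- tabulate(assign, nbins = length(active)) / (nr * nc)
      err <- w - frac
      if (max(abs(err)) < 0.002) break
      delta <- delta + 2 * err
    }
    cls <- matrix(assign, nr, nc)
  }
  landcover <- raster_grid(cls, xmin = 0, ymin = 0, res = scenario$fine_res)
  landcover$levels <- active

  elev_f <- gaussian_field(nr, nc, rng, split_seed(scenario$seed, 201))
  elevation <- raster_grid(pmax(80 + 50 * elev_f, 0),
                           res = scenario$fine_res)

  # population partially tied to the impervious latent field, mimicking the
  # built-up/population correlation of real cities
  pop_f <- gaussian_field(nr, nc, rng, split_seed(scenario$seed, 202))
  imp_idx <- match("impervious", active)
  imp_part <- if (!is.na(imp_idx)) 0.7 * fields[[imp_idx]] else 0
  population <- raster_grid(exp(0.5 + 1.0 * pop_f + imp_part) * 10,
                            res = scenario$fine_res)

  list(landcover = landcover, elevation = elevation, population = population)
}

#' Ground-truth suitability surface for one species
#'
#' Evaluates the known additive suitability function cell by cell on the
#' analysis grid: focal land-cover proportions, sqrt mean altitude and mean
#' population density in a 100 m radius feed the species' effect functions,
#' and the inverse logit of their sum is returned. This is the surface the
#' occurrence generator samples from and the yardstick for parameter
#' recovery.
#'
#' @param landscape output of [generate_landscape()].
#' @param scenario the `SyntheticScenario`.
#' @param species species name present in `scenario$true_coefficients`.
#' @param stack optional precomputed raw predictor stack (from
#'   [build_predictor_stack()] with `standardise = FALSE`); computed if NULL.
#' @return list with `suitability` (`RasterGrid` in \[0, 1\]), `eta` (linear
#'   predictor grid) and `stack` (the raw predictor stack, reusable).
#' @export
true_suitability <- function(landscape, scenario, species, stack = NULL) {
  tc <- scenario$true_coefficients[[species]]
  if (is.null(tc)) stop(sprintf("no true coefficients for species '%s'", species))
  if (is.null(stack))
    stack <- build_predictor_stack(landscape, analysis_res = scenario$analysis_res,
                                   standardise = FALSE)
  eta <- matrix(tc$intercept, grid_nrow(stack$layers[[1]]),
                grid_ncol(stack$layers[[1]]))
  for (nm in names(tc$effects)) {
    lay <- stack$layers[[nm]]
    if (is.null(lay)) stop(sprintf("predictor '%s' not in stack", nm))
    eta <- eta + tc$effects[[nm]](lay$values)
  }
  tpl <- stack$layers[[1]]
  suit <- raster_grid(stats::plogis(eta), tpl$xmin, tpl$ymin, tpl$res)
  list(suitability = suit,
       eta = raster_grid(eta, tpl$xmin, tpl$ymin, tpl$res),
       stack = stack)
}

#' Observer-bias surface
#'
#' A smooth recording-effort surface mimicking urban citizen-science bias:
#' a Gaussian kernel density around a few "city centre" points, rescaled to
#' \[0, 1\] and mapped to `1 + strength * k`, so `strength = 0` gives uniform
#' effort.
#'
#' @param template analysis-resolution `RasterGrid` defining the grid.
#' @param centres n x 2 matrix of effort hotspots (m); default 2 interior points.
#' @param strength bias intensity (>= 0).
#' @param bandwidth_m kernel bandwidth; default a quarter of the extent.
#' @return `RasterGrid` of relative effort (>= 1 at hotspots' scale floor 1).
#' @export
bias_surface <- function(template, centres = NULL, strength = 1, bandwidth_m = NULL) {
  nr <- grid_nrow(template); nc <- grid_ncol(template)
  w <- nc * template$res; h <- nr * template$res
  if (is.null(centres))
    centres <- rbind(c(template$xmin + 0.35 * w, template$ymin + 0.6 * h),
                     c(template$xmin + 0.65 * w, template$ymin + 0.35 * h))
  if (is.null(bandwidth_m)) bandwidth_m <- 0.25 * min(w, h)
  cc <- cell_centres(template)
  k <- rep(0, nrow(cc))
  for (i in seq_len(nrow(centres)))
    k <- k + exp(-((cc$x - centres[i, 1])^2 + (cc$y - centres[i, 2])^2) /
                   (2 * bandwidth_m^2))
  k <- (k - min(k)) / max(max(k) - min(k), .Machine$double.eps)
  raster_grid(matrix(1 + strength * k, nr, nc),
              template$xmin, template$ymin, template$res)
}

#' Simulate occurrence records with a known contamination ledger
#'
#' Clean presences are drawn cell-by-cell with probability proportional to
#' `true suitability x observer bias` (without replacement over cells, so
#' clean records are unique), dated uniformly over the scenario years, and
#' given small coordinate uncertainties. Contaminated records — exact
#' duplicates, high-uncertainty (> 100 m), undated, and out-of-window years —
#' are then injected in known numbers, recorded in the returned ledger so the
#' filtering stage can be checked in closed loop.
#'
#' @param scenario the `SyntheticScenario`.
#' @param suitabilities named list (per species) of suitability `RasterGrid`s
#'   in \[0, 1\] (e.g. from [true_suitability()]).
#' @param bias `RasterGrid` of relative observer effort on the same grid
#'   (NULL = uniform).
#' @return list with `records` (data.frame: species, x, y, year,
#'   uncertainty_m) and `ledger` (per-species and total injected counts).
#' @export
generate_occurrences <- function(scenario, suitabilities, bias = NULL) {
  n <- scenario$n_presence_per_species
  cont <- scenario$contamination
  yrs <- seq(scenario$years[1], scenario$years[2])
  bad_years <- c(seq(scenario$years[1] - 5, scenario$years[1] - 1),
                 seq(scenario$years[2] + 1, scenario$years[2] + 3))
  recs <- list(); ledg <- list()
  for (sp in names(suitabilities)) {
    s <- suitabilities[[sp]]
    if (!is.null(bias)) stop_unless_aligned(s, bias)
    set.seed(split_seed(scenario$seed, 300 + match(sp, names(suitabilities))))
    cc <- cell_centres(s)
    p <- as.vector(s$values) * (if (is.null(bias)) 1 else as.vector(bias$values))
    ok <- which(is.finite(p) & p > 0)
    if (n > length(ok))
      stop(sprintf("requested %d presences but only %d cells have positive weight",
                   n, length(ok)))
    pick <- sample(ok, n, replace = FALSE, prob = p[ok])
    jit <- s$res * 0.3
    clean <- data.frame(
      species = sp,
      x = round(cc$x[pick] + stats::runif(n, -jit, jit), 1),
      y = round(cc$y[pick] + stats::runif(n, -jit, jit), 1),
      year = sample(yrs, n, replace = TRUE),
      uncertainty_m = round(stats::runif(n, 1, 80))
    )
    n_dup <- round(cont[["duplicates"]] * n)
    n_unc <- round(cont[["uncertain"]] * n)
    n_und <- round(cont[["undated"]] * n)
    n_oy  <- round(cont[["out_year"]] * n)

    dup <- clean[sample.int(n, n_dup, replace = TRUE), , drop = FALSE]
    extra_cells <- sample(ok, n_unc + n_oy, replace = TRUE)
    unc <- data.frame(
      species = rep(sp, n_unc),
      x = round(cc$x[extra_cells[seq_len(n_unc)]] + stats::runif(n_unc, -jit, jit), 1),
      y = round(cc$y[extra_cells[seq_len(n_unc)]] + stats::runif(n_unc, -jit, jit), 1),
      year = sample(yrs, n_unc, replace = TRUE),
      uncertainty_m = round(stats::runif(n_unc, 101, 500))
    )
    und <- clean[sample.int(n, n_und, replace = TRUE), , drop = FALSE]
    if (n_und) {
      und$year <- NA_integer_
      und$x <- und$x + 0.1  # not an exact duplicate; removed as undated
    }
    oy_cells <- extra_cells[n_unc + seq_len(n_oy)]
    oy <- data.frame(
      species = rep(sp, n_oy),
      x = round(cc$x[oy_cells] + stats::runif(n_oy, -jit, jit), 1),
      y = round(cc$y[oy_cells] + stats::runif(n_oy, -jit, jit), 1),
      year = sample(bad_years, n_oy, replace = TRUE),
      uncertainty_m = round(stats::runif(n_oy, 1, 80))
    )
    all <- rbind(clean, oy, unc, und, dup)
    recs[[sp]] <- all
    ledg[[sp]] <- c(n_clean = as.integer(n), duplicates = as.integer(n_dup),
                    uncertain = as.integer(n_unc), undated = as.integer(n_und),
                    out_year = as.integer(n_oy), n_total = nrow(all))
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  ledger <- do.call(rbind, ledg)
  total <- colSums(ledger)
  storage.mode(total) <- "integer"
  list(records = records,
       ledger = list(per_species = ledger, total = total))
}

#' Synthetic planner-style corridor polygons
#'
#' A plausible stand-in for an independently produced corridor network:
#' contiguous patches of a source land-cover class at or above a minimum
#' area are linked by straight least-distance links (minimum spanning tree
#' over patch centroids), and patches and links are buffered into polygons.
#'
#' @param landcover fine-resolution categorical `RasterGrid` with `$levels`.
#' @param source_class class name defining habitat patches.
#' @param min_patch_ha minimum patch area (hectares) to qualify as a node.
#' @param buffer_m buffer radius; link polygons are `2 * buffer_m` wide.
#' @return a `polygon_layer` with a `properties` attribute (`kind` =
#'   "patch"/"link"); empty with a warning when no patch qualifies.
#' @export
generate_planner_corridors <- function(landcover, source_class,
                                       min_patch_ha = 0.5, buffer_m = 300) {
  code <- match(source_class, landcover$levels)
  if (is.na(code)) stop(sprintf("class '%s' not present in raster levels", source_class))
  mask <- landcover$values == code
  lab <- label_components(mask, neighbourhood = 8)
  n_comp <- max(lab, 0, na.rm = TRUE)
  if (n_comp == 0) {
    warning("no cells of the source class; empty corridor layer")
    return(polygon_layer())
  }
  cell_area_ha <- landcover$res^2 / 1e4
  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  keep <- which(sizes * cell_area_ha >= min_patch_ha)
  if (!length(keep)) {
    warning("no patch reaches the minimum area; empty corridor layer")
    return(polygon_layer())
  }
  cc <- cell_centres(landcover)
  labv <- as.vector(lab)
  polys <- list(); kind <- character(0)
  centroids <- matrix(NA_real_, length(keep), 2)
  for (i in seq_along(keep)) {
    cells <- which(labv == keep[i])
    xy <- cbind(cc$x[cells], cc$y[cells])
    centroids[i, ] <- colMeans(xy)
    polys[[length(polys) + 1L]] <-
      buffer_hull(xy, buffer_m + landcover$res / 2)
    kind <- c(kind, "patch")
  }
  if (length(keep) >= 2) {
    d <- as.matrix(stats::dist(centroids))
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
    mst <- igraph::mst(g)
    el <- igraph::as_edgelist(mst, names = FALSE)
    for (e in seq_len(nrow(el))) {
      polys[[length(polys) + 1L]] <-
        buffer_segment(centroids[el[e, 1], ], centroids[el[e, 2], ], buffer_m)
      kind <- c(kind, "link")
    }
  }
  out <- polygon_layer(polys)
  attr(out, "properties") <- data.frame(kind = kind)
  out
}
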