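#' Focal-window machinery
#'
#' The analysis grid predictors are focal summaries of the fine-resolution
#' rasters: for each analysis cell, the set of fine cells whose centres lie
#' within `radius_m` of the analysis-cell centre (a disc, including the
#' centre cell) is aggregated. Fine and analysis grids must share the same
#' origin, and the fine cell size must divide the analysis cell size.
#'
#' @name focal
NULL

# Enumerate fine-cell offsets (relative to the analysis cell anchor) whose
# centres fall within radius_m of the analysis cell centre.
disc_offsets <- function(fine_res, ratio, radius_m) {
  halfm <- ratio / 2
  rng_t <- floor(halfm + 0.5 - radius_m / fine_res - 1):
           ceiling(halfm + 0.5 + radius_m / fine_res + 1)
  off <- expand.grid(ti = rng_t, tj = rng_t)
  dx <- (off$tj - 0.5 - halfm) * fine_res
  dy <- (off$ti - 0.5 - halfm) * fine_res
  off[dx^2 + dy^2 <= radius_m^2 + 1e-9, , drop = FALSE]
}

# Accumulate disc sums and finite counts of `vals` (fine matrix) at every
# analysis cell of an nra x nca grid; returns list(sum, count).
focal_accumulate <- function(vals, nra, nca, ratio, offsets) {
  nrf <- nrow(vals); ncf <- ncol(vals)
  fin <- is.finite(vals)
  v0 <- vals; v0[!fin] <- 0
  s <- matrix(0, nra, nca)
  cnt <- matrix(0L, nra, nca)
  ar <- seq_len(nra); ac <- seq_len(nca)
  for (k in seq_len(nrow(offsets))) {
    fr <- (ar - 1L) * ratio + offsets$ti[k]
    fc <- (ac - 1L) * ratio + offsets$tj[k]
    vr <- which(fr >= 1L & fr <= nrf)
    vc <- which(fc >= 1L & fc <= ncf)
    if (!length(vr) || !length(vc)) next
    s[vr, vc] <- s[vr, vc] + v0[fr[vr], fc[vc], drop = FALSE]
    cnt[vr, vc] <- cnt[vr, vc] + fin[fr[vr], fc[vc], drop = FALSE]
  }
  list(sum = s, count = cnt)
}

check_focal_geometry <- function(fine, analysis_res) {
  ratio <- analysis_res / fine$res
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fine cell size must divide the analysis cell size")
  as.integer(round(ratio))
}

#' Focal proportion of land-cover classes
#'
#' Fraction of fine cells, among those with data whose centres lie within
#' `radius_m` of each analysis-cell centre, belonging to `class_set`.
#'
#' @param landcover fine categorical `RasterGrid` with `$levels`.
#' @param class_set character vector of class names.
#' @param radius_m focal radius (m), default 100.
#' @param analysis_res analysis cell size (m).
#' @return analysis-resolution `RasterGrid` in \[0, 1\]; nodata where the
#'   disc holds no valid fine cell.
#' @export
focal_proportion <- function(landcover, class_set, radius_m = 100,
                             analysis_res = 100) {
  ratio <- check_focal_geometry(landcover, analysis_res)
  codes <- match(class_set, landcover$levels)
  if (anyNA(codes))
    stop("unknown classes: ",
         paste(class_set[is.na(codes)], collapse = ", "))
  nra <- nrow(landcover$values) %/% ratio
  nca <- ncol(landcover$values) %/% ratio
  ind <- matrix(as.numeric(landcover$values %in% codes),
                nrow(landcover$values))
  ind[!is.finite(landcover$values)] <- NA_real_
  off <- disc_offsets(landcover$res, ratio, radius_m)
  acc <- focal_accumulate(ind, nra, nca, ratio, off)
  out <- acc$sum / acc$count
  out[acc$count == 0] <- NA_real_
  raster_grid(out, landcover$xmin, landcover$ymin, analysis_res)
}

#' Focal mean with optional transform
#'
#' Mean of a continuous fine raster over the focal disc, with the transform
#' applied after averaging (so `sqrt` is the square root of the disc mean).
#'
#' @param fine fine continuous `RasterGrid`.
#' @param radius_m focal radius (m).
#' @param analysis_res analysis cell size (m).
#' @param transform `"identity"` or `"sqrt"`.
#' @return analysis-resolution `RasterGrid`.
#' @export
focal_mean <- function(fine, radius_m = 100, analysis_res = 100,
                       transform = c("identity", "sqrt")) {
  transform <- match.arg(transform)
  ratio <- check_focal_geometry(fine, analysis_res)
  if (transform == "sqrt" && any(fine$values < 0, na.rm = TRUE))
    stop("sqrt transform requires a nonnegative raster")
  nra <- nrow(fine$values) %/% ratio
  nca <- ncol(fine$values) %/% ratio
  off <- disc_offsets(fine$res, ratio, radius_m)
  acc <- focal_accumulate(fine$values, nra, nca, ratio, off)
  out <- acc$sum / acc$count
  out[acc$count == 0] <- NA_real_
  if (transform == "sqrt") out <- sqrt(out)
  raster_grid(out, fine$xmin, fine$ymin, analysis_res)
}

# mapping from predictor layer names to land-cover classes
LAYER_CLASSES <- list(
  wood = "woodland", wet = "wetland", arable = "arable", grass = "grassland",
  garden = "garden", allot = "allotment", imperv = "impervious"
)

#' Build the analysis-grid predictor stack
#'
#' Seven focal land-cover proportions (`wood`, `wet`, `arable`, `grass`,
#' `garden`, `allot`, `imperv`), square-root focal mean altitude (`alt`) and
#' focal mean population density (`popdensity`), all within a 100 m radius
#' by default, optionally z-scored.
#'
#' @param landscape list with `landcover`, `elevation`, `population`
#'   (as from [generate_landscape()], or read from disk).
#' @param analysis_res analysis cell size (m).
#' @param radius_m focal radius (m).
#' @param standardise z-score layers and store the constants?
#' @return a `PredictorStack`: list with `layers` (named `RasterGrid`s),
#'   `constants` (data.frame layer/mean/sd, or NULL), `radius_m`.
#' @export
build_predictor_stack <- function(landscape, analysis_res = 100,
                                  radius_m = 100, standardise = TRUE) {
  lc <- landscape$landcover
  layers <- list()
  for (nm in names(LAYER_CLASSES)) {
    cls <- intersect(LAYER_CLASSES[[nm]], lc$levels)
    layers[[nm]] <- if (length(cls))
      focal_proportion(lc, cls, radius_m, analysis_res)
    else {
      z <- focal_proportion(lc, lc$levels[1], radius_m, analysis_res)
      z$values[] <- ifelse(is.finite(z$values), 0, NA_real_)
      z
    }
  }
  layers$alt <- focal_mean(landscape$elevation, radius_m, analysis_res, "sqrt")
  layers$popdensity <- focal_mean(landscape$population, radius_m,
                                  analysis_res, "identity")
  stack <- structure(list(layers = layers, constants = NULL,
                          radius_m = radius_m),
                     class = "PredictorStack")
  if (standardise) stack <- standardise_stack(stack) else stack
}

#' Z-score the layers of a predictor stack
#'
#' Subtracts the mean and divides by the sample (n-1) standard deviation of
#' each layer over valid cells. When `constants` is supplied (a data.frame
#' from a previous call) those constants are applied instead of recomputed —
#' used to project new rasters onto the training scale.
#'
#' @param stack a `PredictorStack`.
#' @param constants optional data.frame with columns `layer`, `mean`, `sd`.
#' @return the stack with standardised layers and `constants` filled in.
#' @export
standardise_stack <- function(stack, constants = NULL) {
  nms <- names(stack$layers)
  if (is.null(constants)) {
    constants <- do.call(rbind, lapply(nms, function(nm) {
      v <- stack$layers[[nm]]$values
      v <- v[is.finite(v)]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0)
        stop(sprintf("layer '%s' is constant; cannot standardise", nm))
      data.frame(layer = nm, mean = mean(v), sd = s)
    }))
  }
  for (nm in nms) {
    k <- constants[constants$layer == nm, ]
    if (nrow(k) != 1) stop(sprintf("no standardisation constants for layer '%s'", nm))
    stack$layers[[nm]]$values <-
      (stack$layers[[nm]]$values - k$mean) / k$sd
  }
  stack$constants <- constants
  stack
}

#' Extract stack values at point locations
#'
#' @param stack a `PredictorStack`.
#' @param x,y point coordinates (m).
#' @return data.frame, one column per layer.
#' @export
extract_stack <- function(stack, x, y) {
  as.data.frame(lapply(stack$layers, extract_at, x = x, y = y))
}

#' Spearman collinearity screen
#'
#' Computes pairwise Spearman rank correlations of the stack layers at the
#' supplied points, groups layers whose absolute correlation exceeds the
#' threshold into transitive clusters (graph components), and retains from
#' each cluster the layer that comes first in `keep_preference`.
#'
#' @param stack a `PredictorStack`.
#' @param x,y model-frame point coordinates.
#' @param rho_threshold absolute Spearman correlation above which layers are
#'   considered collinear (default 0.7).
#' @param keep_preference character vector giving a total preference order
#'   over the stack layers; earlier wins. The default puts `garden` ahead of
#'   `imperv` and `popdensity`.
#' @return list with `retained`, `dropped`, `rho` (the Spearman matrix) and
#'   `groups` (cluster membership).
#' @export
correlation_screen <- function(stack, x, y, rho_threshold = 0.7,
                               keep_preference = c("garden", "wood", "wet",
                                                   "grass", "arable", "allot",
                                                   "alt", "imperv",
                                                   "popdensity")) {
  if (length(x) < 3) stop("need at least 3 points for a rank correlation")
  vals <- extract_stack(stack, x, y)
  keep_cols <- vapply(vals, function(v) stats::sd(v, na.rm = TRUE) > 0, logical(1))
  vals <- vals[, keep_cols, drop = FALSE]
  nms <- names(vals)
  if (anyDuplicated(keep_preference))
    stop("keep_preference must be a total order without ties")
  if (!all(nms %in% keep_preference))
    stop("keep_preference must rank every layer: missing ",
         paste(setdiff(nms, keep_preference), collapse = ", "))
  rho <- stats::cor(vals, method = "spearman", use = "pairwise.complete.obs")
  adj <- abs(rho) > rho_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  retained <- character(0)
  for (cm in unique(comp)) {
    members <- nms[comp == cm]
    retained <- c(retained,
                  members[which.min(match(members, keep_preference))])
  }
  retained <- nms[nms %in% retained]  # original layer order
  list(retained = retained, dropped = setdiff(nms, retained),
       rho = rho, groups = split(nms, comp))
}
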