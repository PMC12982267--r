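#' Top-fraction mask of a current (or any) raster
#'
#' Cells with value at or above the `(1 - fraction)` quantile of the finite
#' values; ties at the threshold are included, so on a raster with massed
#' values the mask can exceed the nominal fraction (on an all-constant
#' raster it is every valid cell).
#'
#' @param grid `RasterGrid`.
#' @param fraction fraction of top cells to keep, in (0, 1); default 0.10.
#' @return logical matrix (`NA` cells are FALSE).
#' @export
top_fraction_mask <- function(grid, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  v <- grid$values
  fin <- is.finite(v)
  if (!any(fin)) stop("raster has no valid cells")
  thr <- stats::quantile(v[fin], 1 - fraction, names = FALSE)
  fin & v >= thr
}

#' Four-category corridor gap analysis
#'
#' Rasterises the planner polygons onto the analysis grid (a cell counts as
#' planner corridor when its centre is covered) and labels every valid cell
#' `both`, `species_only`, `planner_only` or `neither` against the
#' species-based corridor mask. Areas are cell counts times cell area,
#' in km^2.
#'
#' @param species_mask logical matrix (e.g. from [top_fraction_mask()]).
#' @param planner polygon layer (`polygon_layer`) in the grid's CRS.
#' @param grid the analysis `RasterGrid` (defines validity and geometry).
#' @return object of class `CategoryPartition`: `labels` (factor matrix
#'   levels both/species_only/planner_only/neither, NA outside valid cells),
#'   `areas_km2` (named), `planner_mask`.
#' @export
gap_analysis <- function(species_mask, planner, grid) {
  valid <- is.finite(grid$values)
  cc <- cell_centres(grid)
  pl <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  if (length(planner) == 0) {
    message("empty planner layer: planner categories are empty")
  } else {
    idx <- which(as.vector(valid))
    pl[idx] <- points_in_layer(cc$x[idx], cc$y[idx], planner)
  }
  sp <- species_mask & valid
  lab <- matrix(NA_character_, nrow(grid$values), ncol(grid$values))
  lab[valid & sp & pl] <- "both"
  lab[valid & sp & !pl] <- "species_only"
  lab[valid & !sp & pl] <- "planner_only"
  lab[valid & !sp & !pl] <- "neither"
  cell_km2 <- grid$res^2 / 1e6
  cats <- c("both", "species_only", "planner_only", "neither")
  areas <- vapply(cats, function(k) sum(lab == k, na.rm = TRUE) * cell_km2,
                  numeric(1))
  structure(list(labels = lab, areas_km2 = areas, planner_mask = pl,
                 species_mask = sp, grid = grid[c("xmin", "ymin", "res")],
                 cell_km2 = cell_km2),
            class = "CategoryPartition")
}

#' @export
print.CategoryPartition <- function(x, ...) {
  cat("CategoryPartition (km^2):\n")
  for (k in names(x$areas_km2))
    cat(sprintf("  %-13s %8.3f\n", k, x$areas_km2[k]))
  invisible(x)
}

category_of_points <- function(partition, grid, x, y) {
  g <- raster_grid(matrix(0, nrow(partition$labels), ncol(partition$labels)),
                   grid$xmin, grid$ymin, grid$res)
  loc <- grid_locate(g, x, y)
  out <- rep(NA_character_, length(x))
  ok <- loc$inside
  out[ok] <- partition$labels[cbind(loc$row[ok], loc$col[ok])]
  out
}

#' Relative probability of presence per corridor category
#'
#' Assigns independent presence records and uniformly drawn background
#' points to the four partition categories by containing cell and reports,
#' per category, the presence fraction divided by the background fraction —
#' a ratio above 1 meaning presences concentrate there more than expected
#' at random. Background points are uniform over valid cells. Categories
#' with zero background fraction get `NA` ratio and are flagged.
#'
#' @param partition a `CategoryPartition`.
#' @param presences data.frame with `x`, `y` of independent records.
#' @param n_background number of uniform background points (default 20000).
#' @param seed integer seed.
#' @return object of class `RelativeProbabilityReport`: data.frame with
#'   category, n_presence, presence_fraction, background_fraction, ratio;
#'   plus `n_presences_used`, `n_dropped_outside`.
#' @export
relative_probability <- function(partition, presences, n_background = 20000,
                                 seed = 1L) {
  if (!nrow(presences)) stop("need at least one presence record")
  g <- partition$grid
  tpl <- raster_grid(matrix(NA_real_, nrow(partition$labels),
                            ncol(partition$labels)),
                     g$xmin, g$ymin, g$res)
  tpl$values[!is.na(partition$labels)] <- 1
  pc <- category_of_points(partition, g, presences$x, presences$y)
  dropped <- sum(is.na(pc))
  pc <- pc[!is.na(pc)]
  if (!length(pc)) stop("all presences fall outside the partition")
  valid_cells <- which(is.finite(as.vector(tpl$values)))
  set.seed(split_seed(seed, 57))
  cc <- cell_centres(tpl)
  bcells <- sample(valid_cells, n_background, replace = TRUE)
  bc <- partition$labels[bcells]
  cats <- c("both", "species_only", "planner_only", "neither")
  tab <- data.frame(
    category = cats,
    n_presence = vapply(cats, function(k) sum(pc == k), numeric(1)),
    n_background = vapply(cats, function(k) sum(bc == k), numeric(1)))
  tab$presence_fraction <- tab$n_presence / length(pc)
  tab$background_fraction <- tab$n_background / n_background
  tab$ratio <- ifelse(tab$background_fraction > 0,
                      tab$presence_fraction / tab$background_fraction,
                      NA_real_)
  structure(list(table = tab, n_presences_used = length(pc),
                 n_dropped_outside = dropped, n_background = n_background,
                 undefined = tab$category[is.na(tab$ratio)]),
            class = "RelativeProbabilityReport")
}

#' @export
print.RelativeProbabilityReport <- function(x, ...) {
  cat(sprintf("RelativeProbabilityReport (%d presences, %d background):\n",
              x$n_presences_used, x$n_background))
  print(x$table[, c("category", "presence_fraction", "background_fraction",
                    "ratio")], row.names = FALSE)
  invisible(x)
}

#' Descriptive statistics per corridor category
#'
#' Per partition category: mean and median Euclidean distance of member
#' cell centres to a reference centre point, and the land-cover class
#' composition of the member cells (fraction of fine cells of each class
#' within them).
#'
#' @param partition a `CategoryPartition`.
#' @param landcover fine categorical `RasterGrid` with `$levels`.
#' @param centre length-2 numeric (x, y) of the reference point (the "city
#'   centre").
#' @return list with `distance` (data.frame per category) and `landcover`
#'   (category x class fraction matrix); empty categories yield NaN rows.
#' @export
corridor_descriptives <- function(partition, landcover, centre) {
  g <- partition$grid
  tpl <- raster_grid(matrix(0, nrow(partition$labels), ncol(partition$labels)),
                     g$xmin, g$ymin, g$res)
  cc <- cell_centres(tpl)
  labv <- as.vector(partition$labels)
  cats <- c("both", "species_only", "planner_only", "neither")
  dist_tab <- do.call(rbind, lapply(cats, function(k) {
    sel <- which(labv == k)
    d <- sqrt((cc$x[sel] - centre[1])^2 + (cc$y[sel] - centre[2])^2)
    data.frame(category = k, n_cells = length(sel),
               mean_dist_m = mean(d), median_dist_m = stats::median(d))
  }))
  ratio <- check_focal_geometry(landcover, g$res)
  lcv <- landcover$values
  lc_tab <- matrix(NA_real_, length(cats), length(landcover$levels),
                   dimnames = list(cats, landcover$levels))
  # analysis cell (i, j) covers the fine block rows (i-1)*ratio+1 .. i*ratio
  arow <- (row(lcv) - 1L) %/% ratio + 1L
  acol <- (col(lcv) - 1L) %/% ratio + 1L
  acell <- (acol - 1L) * nrow(partition$labels) + arow
  fine_lab <- labv[acell]
  for (k in cats) {
    sel <- fine_lab == k & !is.na(fine_lab) & is.finite(lcv)
    n <- sum(sel)
    if (n > 0)
      lc_tab[k, ] <- tabulate(lcv[sel], nbins = length(landcover$levels)) / n
  }
  list(distance = dist_tab, landcover = lc_tab)
}

#' Pinch-cluster overlap with planner corridors
#'
#' A cluster counts as overlapping when any member cell centre falls inside
#' a planner polygon; the whole cluster's area is then attributed to the
#' overlap (whole-cluster rule, matching cluster-count reporting).
#'
#' @param pinch_set a `PinchPointSet`.
#' @param planner a `polygon_layer`.
#' @param grid the `RasterGrid` the clusters live on.
#' @return list: `n_in`, `n_out`, `area_in_km2`, `area_out_km2`,
#'   `overlapping` (logical per cluster).
#' @export
pinch_overlap <- function(pinch_set, planner, grid) {
  ncl <- length(pinch_set$members)
  if (ncl == 0)
    return(list(n_in = 0L, n_out = 0L, area_in_km2 = 0, area_out_km2 = 0,
                overlapping = logical(0)))
  cc <- cell_centres(grid)
  overl <- vapply(pinch_set$members, function(m)
    length(planner) > 0 && any(points_in_layer(cc$x[m], cc$y[m], planner)),
    logical(1))
  a <- pinch_set$clusters$area_m2 / 1e6
  list(n_in = sum(overl), n_out = sum(!overl),
       area_in_km2 = sum(a[overl]), area_out_km2 = sum(a[!overl]),
       overlapping = overl)
}
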