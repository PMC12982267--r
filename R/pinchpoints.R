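#' Cost-weighted distance from a source core
#'
#' Exact least accumulated movement cost from the source cells to every
#' reachable cell, by Dijkstra's algorithm over the resistance lattice. The
#' cost of stepping between neighbouring cells i, j is
#' `d_ij * (r_i + r_j) / 2 * cell_size` with `d_ij` in cell units (1
#' orthogonal, sqrt(2) diagonal).
#'
#' @param resistance `RasterGrid` of positive resistances.
#' @param source_cells linear cell indices of the source core (cost 0).
#' @param neighbourhood 8 (default) or 4.
#' @param cell_size_m cell size used to scale costs; defaults to the grid
#'   resolution. Pass 1 for costs in cell units.
#' @return `RasterGrid` of accumulated costs (0 on the source, `Inf` where
#'   unreachable, NA on nodata).
#' @export
cost_distance <- function(resistance, source_cells, neighbourhood = 8,
                          cell_size_m = resistance$res) {
  if (!length(source_cells)) stop("source must be non-empty")
  graph <- build_lattice_graph(resistance, neighbourhood)
  src <- match(source_cells, graph$cells)
  if (anyNA(src)) stop("source cells fall on nodata")
  g <- igraph::make_empty_graph(n = length(graph$cells), directed = FALSE)
  g <- igraph::add_edges(g, rbind(graph$edges$a, graph$edges$b))
  w <- cell_size_m / graph$edges$conductance
  d <- igraph::distances(g, v = src, weights = w, algorithm = "dijkstra")
  dmin <- if (length(src) > 1) apply(d, 2, min) else as.numeric(d)
  out <- matrix(NA_real_, graph$nrow, graph$ncol)
  out[graph$cells] <- dmin
  raster_grid(out, resistance$xmin, resistance$ymin, resistance$res)
}

#' Least-cost corridor between two cost-distance fields
#'
#' The least-cost-path (LCP) cost between cores A and B is the minimum over
#' cells of `cwd_A + cwd_B`; the corridor is the band of cells whose summed
#' cost is within `cutoff` of it.
#'
#' @param cwd_a,cwd_b aligned `RasterGrid`s from [cost_distance()].
#' @param cutoff corridor width on the cost scale (0 = the LCP cells only;
#'   `Inf` = all mutually reachable cells).
#' @return list with `mask` (logical matrix), `lcp_cost`, and `total`
#'   (the summed cost grid).
#' @export
least_cost_corridor <- function(cwd_a, cwd_b, cutoff) {
  stop_unless_aligned(cwd_a, cwd_b, what = "cost fields")
  total <- cwd_a$values + cwd_b$values
  fin <- is.finite(total)
  if (!any(fin)) {
    warning("no finite cell; empty corridor")
    return(list(mask = fin & FALSE, lcp_cost = Inf, total = total))
  }
  lcp <- min(total[fin])
  mask <- fin & total <= lcp + cutoff
  list(mask = mask, lcp_cost = lcp, total = total)
}

#' Circuit solve restricted to a corridor
#'
#' Masks the resistance surface to the corridor cells (plus the two cores)
#' and runs the pair solve there; cells outside the corridor are treated as
#' nodata.
#'
#' @param resistance `RasterGrid` of positive resistances.
#' @param corridor_mask logical matrix over the same grid.
#' @param source_cells,target_cells linear cell indices of the pair's cores.
#' @param neighbourhood 8 (default) or 4.
#' @return as [solve_pair()].
#' @export
corridor_current <- function(resistance, corridor_mask, source_cells,
                             target_cells, neighbourhood = 8) {
  r <- resistance
  keep <- corridor_mask
  keep[c(source_cells, target_cells)] <- TRUE
  r$values[!keep] <- NA_real_
  graph <- build_lattice_graph(r, neighbourhood)
  solve_pair(graph, source_cells, target_cells)
}

#' Extract pinch-point clusters from a current map
#'
#' Thresholds the finite current values at the stated percentile and groups
#' the cells at or above it by adjacency; clusters smaller than `min_cells`
#' are discarded. On an all-constant raster the percentile is degenerate and
#' no cluster is returned (with a warning).
#'
#' @param current `RasterGrid` (or plain matrix) of per-cell current.
#' @param percentile percentile defining "top" cells (default 99 = top 1%).
#' @param min_cells minimum cluster size (default 2).
#' @param neighbourhood 8 (default) or 4.
#' @param cell_area_m2 cell area for cluster areas; taken from the grid when
#'   available.
#' @return object of class `PinchPointSet`: `clusters` data.frame (id,
#'   n_cells, area_m2, max_current, mean_current), `labels` matrix,
#'   `members` list of cell indices, `threshold`.
#' @export
extract_pinch_points <- function(current, percentile = 99, min_cells = 2,
                                 neighbourhood = 8, cell_area_m2 = NULL) {
  v <- if (inherits(current, "RasterGrid")) current$values else current
  if (is.null(cell_area_m2))
    cell_area_m2 <- if (inherits(current, "RasterGrid")) current$res^2 else 1
  fin <- is.finite(v)
  if (sum(fin) < 100)
    warning("fewer than 100 finite cells; percentile threshold is unstable")
  vals <- v[fin]
  if (!length(vals) || max(vals) == min(vals)) {
    warning("constant current raster; degenerate percentile, no clusters")
    return(empty_pinch_set(v))
  }
  thr <- stats::quantile(vals, percentile / 100, names = FALSE)
  mask <- fin & v >= thr
  lab <- label_components(mask, neighbourhood)
  n_comp <- max(lab)
  if (n_comp == 0) return(empty_pinch_set(v, thr))
  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  keep <- which(sizes >= min_cells)
  members <- lapply(keep, function(k) which(lab == k))
  labels <- matrix(0L, nrow(v), ncol(v))
  for (i in seq_along(members)) labels[members[[i]]] <- i
  clusters <- data.frame(
    id = seq_along(members),
    n_cells = lengths(members),
    area_m2 = lengths(members) * cell_area_m2,
    max_current = vapply(members, function(m) max(v[m]), numeric(1)),
    mean_current = vapply(members, function(m) mean(v[m]), numeric(1)))
  structure(list(clusters = clusters, labels = labels, members = members,
                 threshold = thr),
            class = "PinchPointSet")
}

empty_pinch_set <- function(v, thr = NA_real_) {
  structure(list(clusters = data.frame(id = integer(0), n_cells = integer(0),
                                       area_m2 = numeric(0),
                                       max_current = numeric(0),
                                       mean_current = numeric(0)),
                 labels = matrix(0L, nrow(v), ncol(v)),
                 members = list(), threshold = thr),
            class = "PinchPointSet")
}

#' Full pinch-point analysis between critical core areas
#'
#' Delineates critical cores (suitability above `tau_critical`), builds
#' least-cost corridors between every mutually reachable pair, runs the
#' corridor-restricted circuit solve per pair, extracts each pair's top-
#' percentile current cells, merges them across pairs, and reports the
#' merged clusters (two or more neighbouring cells in the top 1% of pinch
#' values, by default).
#'
#' @param resistance `RasterGrid` of positive resistances.
#' @param combined combined suitability `RasterGrid` in \[0, 1\].
#' @param tau_critical critical-core threshold (default 0.9).
#' @param corridor_cutoff corridor width on the cost scale; default
#'   `5 * mean resistance * cell size` (five average cell crossings).
#' @param percentile pinch percentile within corridor cells (default 99).
#' @param min_cells minimum cluster size (default 2).
#' @param neighbourhood 8 (default) or 4.
#' @return list with `clusters` (a `PinchPointSet` over the merged map),
#'   `pinch_current` (`RasterGrid`: max per-pair corridor current),
#'   `cores` (the critical `CoreAreaSet`), `pairs` (per-pair diagnostics).
#' @export
pinch_point_analysis <- function(resistance, combined, tau_critical = 0.9,
                                 corridor_cutoff = NULL, percentile = 99,
                                 min_cells = 2, neighbourhood = 8) {
  cores <- delineate_core_areas(combined, tau = tau_critical,
                                min_cells = min_cells, link_dist_m = Inf,
                                neighbourhood = neighbourhood)
  ng <- length(cores$groups)
  if (ng < 2) stop("need >= 2 critical core areas for a pinch-point analysis")
  if (is.null(corridor_cutoff))
    corridor_cutoff <- 5 * mean(resistance$values[is.finite(resistance$values)]) *
      resistance$res
  cwd <- lapply(cores$groups, function(g)
    cost_distance(resistance, g, neighbourhood))
  nr <- nrow(resistance$values); nc <- ncol(resistance$values)
  pinch <- matrix(0, nr, nc)
  hit <- matrix(FALSE, nr, nc)
  pair_info <- list()
  top_cells <- integer(0)
  for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
    corr <- least_cost_corridor(cwd[[i]], cwd[[j]], corridor_cutoff)
    if (!is.finite(corr$lcp_cost) || !any(corr$mask)) next
    sol <- corridor_current(resistance, corr$mask, cores$groups[[i]],
                            cores$groups[[j]], neighbourhood)
    if (!sol$reachable) next
    cur <- sol$current
    cur[c(cores$groups[[i]], cores$groups[[j]])] <- NA_real_
    inb <- which(is.finite(cur) & corr$mask)
    if (!length(inb)) next
    thr <- stats::quantile(cur[inb], percentile / 100, names = FALSE)
    top_cells <- union(top_cells, inb[cur[inb] >= thr])
    sel <- is.finite(cur)
    pinch[sel] <- pmax(pinch[sel], cur[sel])
    hit <- hit | sel | corr$mask
    pair_info[[length(pair_info) + 1L]] <- data.frame(
      i = i, j = j, lcp_cost = corr$lcp_cost,
      effective_resistance = sol$effective_resistance,
      n_corridor_cells = sum(corr$mask))
  }
  if (!length(pair_info)) stop("no pair produced a usable corridor")
  pinch[!hit] <- NA_real_
  mask <- matrix(FALSE, nr, nc); mask[top_cells] <- TRUE
  lab <- label_components(mask, neighbourhood)
  n_comp <- max(lab)
  members <- list()
  if (n_comp > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n_comp)
    members <- lapply(which(sizes >= min_cells), function(k) which(lab == k))
  }
  labels <- matrix(0L, nr, nc)
  for (k in seq_along(members)) labels[members[[k]]] <- k
  clusters <- structure(list(
    clusters = data.frame(
      id = seq_along(members), n_cells = lengths(members),
      area_m2 = lengths(members) * resistance$res^2,
      max_current = vapply(members, function(m) max(pinch[m], na.rm = TRUE),
                           numeric(1)),
      mean_current = vapply(members, function(m) mean(pinch[m], na.rm = TRUE),
                            numeric(1))),
    labels = labels, members = members, threshold = NA_real_),
    class = "PinchPointSet")
  list(clusters = clusters,
       pinch_current = raster_grid(pinch, resistance$xmin, resistance$ymin,
                                   resistance$res),
       cores = cores, corridor_cutoff = corridor_cutoff,
       pairs = do.call(rbind, pair_info))
}

#' Convex-hull polygons for pinch-point clusters
#'
#' A reporting convenience: each cluster becomes the convex hull of its cell
#' squares (cell centres buffered by half a cell).
#'
#' @param pinch_set a `PinchPointSet`.
#' @param grid the `RasterGrid` the clusters live on.
#' @return a `polygon_layer` with the cluster table as properties.
#' @export
pinch_polygons <- function(pinch_set, grid) {
  cc <- cell_centres(grid)
  polys <- lapply(pinch_set$members, function(m)
    buffer_hull(cbind(cc$x[m], cc$y[m]), grid$res / 2, n_arc = 8))
  out <- polygon_layer(polys)
  attr(out, "properties") <- pinch_set$clusters
  out
}
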