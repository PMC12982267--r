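# Enumerate adjacent cell pairs (linear, column-major indices) of a logical
# matrix under rook (4) or queen (8) adjacency. Returns a data.frame with the
# pair indices and the centre-to-centre distance in cell units (1 or sqrt(2)).
adjacency_pairs <- function(mask, neighbourhood = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (neighbourhood == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  else if (neighbourhood != 4) stop("neighbourhood must be 4 or 8")
  out <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    di <- offs[[k]][1]; dj <- offs[[k]][2]
    ri <- seq_len(nr - di)
    cj <- if (dj >= 0) seq_len(nc - dj) else seq(1 - dj, nc)
    m1 <- mask[ri, cj, drop = FALSE]
    m2 <- mask[ri + di, cj + dj, drop = FALSE]
    ok <- which(m1 & m2, arr.ind = TRUE)
    if (!nrow(ok)) next
    r1 <- ri[ok[, 1]]; c1 <- cj[ok[, 2]]
    out[[k]] <- data.frame(
      a = (c1 - 1L) * nr + r1,
      b = (c1 + dj - 1L) * nr + r1 + di,
      d = sqrt(di^2 + dj^2))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(a = integer(0), b = integer(0), d = numeric(0))
  else res
}

#' Label connected components of a logical matrix
#'
#' @param mask logical matrix (NA treated as FALSE).
#' @param neighbourhood 8 (queen) or 4 (rook) adjacency.
#' @return integer matrix of component labels (0 outside the mask).
#' @export
label_components <- function(mask, neighbourhood = 8) {
  mask[is.na(mask)] <- FALSE
  cells <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(cells)) return(lab)
  ap <- adjacency_pairs(mask, neighbourhood)
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (nrow(ap)) {
    idx <- match(c(ap$a, ap$b), cells)
    g <- igraph::add_edges(g, rbind(idx[seq_len(nrow(ap))],
                                    idx[nrow(ap) + seq_len(nrow(ap))]))
  }
  lab[cells] <- igraph::components(g)$membership
  lab
}

#' Convert combined suitability to a movement-resistance surface
#'
#' Resistance is the multiplicative inverse of suitability, floored at
#' `epsilon` so fully unsuitable cells get finite resistance `1/epsilon`
#' (the circuit-theory cost convention); `mode = "linear"` gives the
#' complement `1 - s + epsilon` instead.
#'
#' @param combined `RasterGrid` of combined suitability in \[0, 1\].
#' @param epsilon positive suitability floor (default 1e-3).
#' @param mode `"inverse"` (default) or `"linear"`.
#' @return `RasterGrid` of per-cell resistance (> 0), with fields `epsilon`
#'   and `provenance` recording how it was built.
#' @export
suitability_to_resistance <- function(combined, epsilon = 1e-3,
                                      mode = c("inverse", "linear")) {
  mode <- match.arg(mode)
  if (epsilon <= 0) stop("epsilon must be positive")
  v <- combined$values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("combined suitability must lie in [0, 1]")
  r <- if (mode == "inverse") 1 / pmax(v, epsilon) else 1 - v + epsilon
  out <- raster_grid(r, combined$xmin, combined$ymin, combined$res)
  out$epsilon <- epsilon
  out$provenance <- if (mode == "inverse") "inverse-suitability" else "direct"
  out
}

#' Delineate core habitat areas
#'
#' Core areas are the circuit nodes: groups of `min_cells` or more adjacent
#' cells (queen adjacency by default) with combined suitability at or above
#' `tau`. Groups farther than `link_dist_m` (centre-to-centre) from every
#' other surviving group are handled per `isolated`: dropped (default,
#' reading the linkage distance as an isolation filter) or merged into
#' multi-patch nodes; a single surviving group is kept as is.
#'
#' @param combined `RasterGrid` in \[0, 1\].
#' @param tau suitability threshold (0.5 for core, 0.9 for critical core).
#' @param min_cells minimum group size (default 2).
#' @param link_dist_m linkage distance (default 300 m).
#' @param neighbourhood 8 or 4.
#' @param isolated `"drop"` or `"merge"`.
#' @return object of class `CoreAreaSet`: `labels` matrix, `groups` (list of
#'   cell index vectors), the parameters, and `area_km2`.
#' @export
delineate_core_areas <- function(combined, tau = 0.5, min_cells = 2,
                                 link_dist_m = 300, neighbourhood = 8,
                                 isolated = c("drop", "merge")) {
  isolated <- match.arg(isolated)
  mask <- !is.na(combined$values) & combined$values >= tau
  lab <- label_components(mask, neighbourhood)
  n_comp <- max(lab)
  groups <- list()
  if (n_comp > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n_comp)
    keep <- which(sizes >= min_cells)
    groups <- lapply(keep, function(k) which(lab == k))
  }
  if (length(groups) >= 2 && is.finite(link_dist_m)) {
    cc <- cell_centres(combined)
    gxy <- lapply(groups, function(g) cbind(cc$x[g], cc$y[g]))
    ng <- length(groups)
    near <- matrix(FALSE, ng, ng)
    for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
      dmin <- min(sqrt(outer(gxy[[i]][, 1], gxy[[j]][, 1], "-")^2 +
                       outer(gxy[[i]][, 2], gxy[[j]][, 2], "-")^2))
      near[i, j] <- near[j, i] <- dmin <= link_dist_m
    }
    if (isolated == "drop") {
      groups <- groups[rowSums(near) > 0]
    } else {
      g <- igraph::graph_from_adjacency_matrix(near, mode = "undirected")
      mem <- igraph::components(g)$membership
      groups <- lapply(unique(mem), function(m)
        sort(unlist(groups[mem == m])))
    }
  }
  if (!length(groups)) warning("no qualifying core area")
  labels <- matrix(0L, nrow(combined$values), ncol(combined$values))
  for (i in seq_along(groups)) labels[groups[[i]]] <- i
  structure(list(labels = labels, groups = groups, tau = tau,
                 min_cells = min_cells, link_dist_m = link_dist_m,
                 neighbourhood = neighbourhood, isolated = isolated,
                 area_km2 = sum(lengths(groups)) * combined$res^2 / 1e6,
                 grid = combined[c("xmin", "ymin", "res")]),
            class = "CoreAreaSet")
}

#' @export
print.CoreAreaSet <- function(x, ...) {
  cat(sprintf("CoreAreaSet: %d groups (tau >= %g, >= %d cells, link %g m), %.3g km^2\n",
              length(x$groups), x$tau, x$min_cells, x$link_dist_m, x$area_km2))
  invisible(x)
}

#' Build the conductance lattice over a resistance surface
#'
#' Nodes are the finite cells; neighbouring cells i, j are joined by an edge
#' of conductance `1 / (d_ij * (r_i + r_j) / 2)` with `d_ij` the
#' centre-to-centre distance in cell units (1 orthogonal, sqrt(2) diagonal) —
#' the mean-resistance edge rule. Disconnected surfaces are allowed; the
#' component labels are carried on the graph.
#'
#' @param resistance `RasterGrid` of positive resistances (NA = nodata).
#' @param neighbourhood 8 (default) or 4.
#' @return object of class `lattice_graph`: `cells` (linear indices of
#'   nodes), `edges` (data.frame a, b as node ids, conductance, d),
#'   `component` (per node), grid geometry.
#' @export
build_lattice_graph <- function(resistance, neighbourhood = 8) {
  v <- resistance$values
  if (any(v <= 0, na.rm = TRUE)) stop("resistances must be positive")
  cells <- which(is.finite(v))
  if (length(cells) < 2) stop("need at least 2 valid cells")
  ap <- adjacency_pairs(is.finite(v), neighbourhood)
  a <- match(ap$a, cells); b <- match(ap$b, cells)
  cond <- 1 / (ap$d * (v[ap$a] + v[ap$b]) / 2)
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (length(a)) g <- igraph::add_edges(g, rbind(a, b))
  comp <- igraph::components(g)$membership
  structure(list(cells = cells, edges = data.frame(a = a, b = b,
                                                   conductance = cond,
                                                   d = ap$d),
                 component = comp, nrow = nrow(v), ncol = ncol(v),
                 xmin = resistance$xmin, ymin = resistance$ymin,
                 res = resistance$res),
            class = "lattice_graph")
}

#' Solve the circuit between one source/target core pair
#'
#' Cells of each core are short-circuited into a single supernode; the
#' graph-Laplacian system `L v = i` is solved with `+injection` at the
#' source supernode and the target supernode grounded. Per-cell current is
#' half the sum of absolute currents on the edges incident to the cell;
#' effective resistance is the source-target voltage difference per unit
#' injected current.
#'
#' @param graph a `lattice_graph`.
#' @param source_cells,target_cells linear cell indices (into the raster
#'   matrix) of the two cores; non-empty and disjoint.
#' @param injection injected current (default 1).
#' @return list with `current` (matrix, NA at nodata), `voltage` (matrix),
#'   `effective_resistance`, `reachable` (FALSE when the cores sit in
#'   different graph components: infinite resistance, zero currents).
#' @export
solve_pair <- function(graph, source_cells, target_cells, injection = 1) {
  if (!length(source_cells) || !length(target_cells))
    stop("source and target must be non-empty")
  if (length(intersect(source_cells, target_cells)))
    stop("source and target cells overlap")
  s_nodes <- match(source_cells, graph$cells)
  t_nodes <- match(target_cells, graph$cells)
  if (anyNA(s_nodes) || anyNA(t_nodes))
    stop("core cells fall outside the graph (nodata)")
  nmat <- function(vals) {
    m <- matrix(NA_real_, graph$nrow, graph$ncol)
    m[graph$cells] <- vals
    m
  }
  if (!any(graph$component[s_nodes][1] == graph$component[t_nodes])) {
    return(list(current = nmat(0), voltage = nmat(NA_real_),
                effective_resistance = Inf, reachable = FALSE))
  }
  n <- length(graph$cells)
  super <- seq_len(n)
  super[s_nodes] <- s_nodes[1]
  super[t_nodes] <- t_nodes[1]
  ids <- match(super, sort(unique(super)))
  s_id <- ids[s_nodes[1]]; t_id <- ids[t_nodes[1]]
  m <- max(ids)
  ea <- ids[graph$edges$a]; eb <- ids[graph$edges$b]
  keep <- ea != eb
  A <- Matrix::sparseMatrix(i = c(ea[keep], eb[keep]),
                            j = c(eb[keep], ea[keep]),
                            x = rep(graph$edges$conductance[keep], 2),
                            dims = c(m, m))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  free <- setdiff(seq_len(m), t_id)
  rhs <- rep(0, m); rhs[s_id] <- injection
  v_free <- Matrix::solve(L[free, free], rhs[free])
  volt <- rep(0, m)
  volt[free] <- as.numeric(v_free)
  v_node <- volt[ids]
  i_edge <- graph$edges$conductance * (v_node[graph$edges$a] - v_node[graph$edges$b])
  cur <- rep(0, n)
  tab_a <- tapply(abs(i_edge), graph$edges$a, sum)
  tab_b <- tapply(abs(i_edge), graph$edges$b, sum)
  cur[as.integer(names(tab_a))] <- cur[as.integer(names(tab_a))] + tab_a
  cur[as.integer(names(tab_b))] <- cur[as.integer(names(tab_b))] + tab_b
  cur <- cur / 2
  list(current = nmat(cur), voltage = nmat(v_node),
       effective_resistance = (volt[s_id] - volt[t_id]) / injection,
       reachable = TRUE)
}

#' All-pairs cumulative current map
#'
#' Sums the per-cell current over every unordered pair of core areas; for
#' each pair the cells belonging to that pair's cores are excluded from its
#' contribution (interior core currents are artefacts of the supernode
#' collapse). Pairs in different graph components contribute nothing and
#' are reported with infinite effective resistance.
#'
#' @param resistance `RasterGrid` of positive resistances.
#' @param cores a `CoreAreaSet` with >= 2 groups.
#' @param neighbourhood 8 (default) or 4.
#' @param pairs optional 2-column matrix of group indices to solve (default
#'   all unordered pairs).
#' @return object of class `CurrentMap`: `current` (`RasterGrid`),
#'   `effective_resistance` (symmetric matrix), `pairs`, `graph`.
#' @export
cumulative_current <- function(resistance, cores, neighbourhood = 8,
                               pairs = NULL) {
  ng <- length(cores$groups)
  if (ng < 2) stop("need >= 2 core areas (nodes)")
  graph <- build_lattice_graph(resistance, neighbourhood)
  if (is.null(pairs)) pairs <- t(utils::combn(ng, 2))
  acc <- matrix(0, nrow(resistance$values), ncol(resistance$values))
  reff <- matrix(NA_real_, ng, ng)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    sol <- solve_pair(graph, cores$groups[[i]], cores$groups[[j]])
    reff[i, j] <- reff[j, i] <- sol$effective_resistance
    if (sol$reachable) {
      contrib <- sol$current
      contrib[c(cores$groups[[i]], cores$groups[[j]])] <- 0
      contrib[is.na(contrib)] <- 0
      acc <- acc + contrib
    }
  }
  acc[!is.finite(resistance$values)] <- NA_real_
  structure(list(
    current = raster_grid(acc, resistance$xmin, resistance$ymin,
                          resistance$res),
    effective_resistance = reff, pairs = pairs, graph = graph),
    class = "CurrentMap")
}
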