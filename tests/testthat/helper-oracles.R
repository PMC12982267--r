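# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own adjacency / labelling / solver code paths.

# Dense Laplacian-pseudoinverse circuit oracle on a resistance matrix.
# Source/target are single linear (column-major) cell indices; NA = nodata.
# Returns voltages (target grounded) and the effective resistance.
dense_circuit_oracle <- function(rmat, source, target, neighbourhood = 8,
                                 injection = 1) {
  nr <- nrow(rmat); nc <- ncol(rmat)
  cells <- which(is.finite(rmat))
  id <- match(seq_len(nr * nc), cells)
  n <- length(cells)
  G <- matrix(0, n, n)
  for (cell in cells) {
    r0 <- (cell - 1) %% nr + 1
    c0 <- (cell - 1) %/% nr + 1
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      if (neighbourhood == 4 && di != 0 && dj != 0) next
      r1 <- r0 + di; c1 <- c0 + dj
      if (r1 < 1 || r1 > nr || c1 < 1 || c1 > nc) next
      other <- (c1 - 1) * nr + r1
      if (!is.finite(rmat[other])) next
      d <- sqrt(di^2 + dj^2)
      g <- 1 / (d * (rmat[cell] + rmat[other]) / 2)
      G[id[cell], id[other]] <- g
    }
  }
  L <- diag(rowSums(G)) - G
  i_vec <- rep(0, n)
  i_vec[id[source]] <- injection
  i_vec[id[target]] <- -injection
  v <- drop(MASS::ginv(L) %*% i_vec)
  v <- v - v[id[target]]
  list(voltage = v, cells = cells,
       effective_resistance = (v[id[source]] - v[id[target]]) / injection)
}

# Exhaustive simple-path least-cost oracle (4-neighbour lattice): minimum
# accumulated cost from `source` (linear index) to every cell by depth-first
# enumeration of all simple paths. Edge cost d * (r_i + r_j) / 2 * cell_size.
enumerate_cost_oracle <- function(rmat, source, cell_size = 1) {
  nr <- nrow(rmat); nc <- ncol(rmat)
  ncell <- nr * nc
  best <- rep(Inf, ncell)
  best[source] <- 0
  visited <- rep(FALSE, ncell)
  neigh <- function(cell) {
    r0 <- (cell - 1) %% nr + 1; c0 <- (cell - 1) %/% nr + 1
    out <- integer(0)
    if (r0 > 1) out <- c(out, cell - 1)
    if (r0 < nr) out <- c(out, cell + 1)
    if (c0 > 1) out <- c(out, cell - nr)
    if (c0 < nc) out <- c(out, cell + nr)
    out[is.finite(rmat[out])]
  }
  dfs <- function(cell, cost) {
    visited[cell] <<- TRUE
    for (nb in neigh(cell)) {
      if (visited[nb]) next
      step <- (rmat[cell] + rmat[nb]) / 2 * cell_size
      nco <- cost + step
      if (nco < best[nb]) best[nb] <<- nco
      dfs(nb, nco)
    }
    visited[cell] <<- FALSE
  }
  if (is.finite(rmat[source])) dfs(source, 0)
  best[!is.finite(rmat)] <- NA_real_
  best
}

# Independent flood-fill component labelling (stack-based, no igraph).
flood_fill_oracle <- function(mask, neighbourhood = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- (cell - 1) %% nr + 1; c0 <- (cell - 1) %/% nr + 1
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        if (neighbourhood == 4 && di != 0 && dj != 0) next
        r1 <- r0 + di; c1 <- c0 + dj
        if (r1 < 1 || r1 > nr || c1 < 1 || c1 > nc) next
        nb <- (c1 - 1) * nr + r1
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
  }
  lab
}

# Independent even-odd ray-casting point-in-polygon (single ring, open).
ray_cast_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# A tiny landscape + records fixture shared by several tests.
small_scenario <- function(seed = 42, n_presence = 100, ...) {
  synthetic_scenario(seed = seed, extent = c(1600, 1600), fine_res = 20,
                     analysis_res = 100, smoothness = 300,
                     n_presence_per_species = n_presence, ...)
}

grid_from <- function(values, res = 100, xmin = 0, ymin = 0) {
  raster_grid(matrix(values[[1]], nrow = values[[2]], ncol = values[[3]]),
              xmin = xmin, ymin = ymin, res = res)
}
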