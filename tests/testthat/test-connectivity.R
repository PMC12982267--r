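test_that("resistance is the floored multiplicative inverse of suitability", {
  s <- raster_grid(matrix(c(1, 0.5, 0, NA), 2, 2), res = 100)
  r <- suitability_to_resistance(s, epsilon = 1e-3)
  expect_equal(r$values[1, 1], 1)
  expect_equal(r$values[2, 1], 2)
  expect_equal(r$values[1, 2], 1000)       # floored at 1/epsilon
  expect_true(is.na(r$values[2, 2]))
  expect_error(suitability_to_resistance(s, epsilon = 0), "positive")
  lin <- suitability_to_resistance(s, mode = "linear")
  expect_equal(lin$values[2, 1], 0.501)
})

test_that("core delineation enforces group size, adjacency and linkage distance", {
  m <- matrix(0, 10, 10)
  m[2, 2] <- 0.9                         # isolated single cell: excluded
  m[5, 5] <- 0.8; m[6, 6] <- 0.8         # diagonal pair: one queen group
  g <- raster_grid(m, res = 100)
  cores <- delineate_core_areas(g, tau = 0.5, min_cells = 2,
                                link_dist_m = Inf)
  expect_equal(length(cores$groups), 1)
  expect_equal(sort(cores$groups[[1]]),
               sort(c((5 - 1) * 10 + 5, (6 - 1) * 10 + 6)))
  # rook adjacency splits the diagonal pair below min size
  expect_warning(
    rook <- delineate_core_areas(g, tau = 0.5, min_cells = 2,
                                 link_dist_m = Inf, neighbourhood = 4),
    "no qualifying")
  expect_equal(length(rook$groups), 0)

  # three groups, one 400 m from the others (100 m cells): dropped by the
  # 300 m linkage rule; distances checked brute force
  m3 <- matrix(0, 12, 12)
  m3[2, 2:3] <- 1          # group A
  m3[2, 6:7] <- 1          # group B: 300 m from A (cols 3 -> 6)
  m3[8, 2:3] <- 1          # group C: 500 m South of A? rows 2 -> 8 = 600 m
  g3 <- raster_grid(m3, res = 100)
  all3 <- delineate_core_areas(g3, tau = 0.5, link_dist_m = Inf)
  expect_equal(length(all3$groups), 3)
  cc <- cell_centres(g3)
  dmin <- function(a, b) min(sqrt(outer(cc$x[a], cc$x[b], "-")^2 +
                                  outer(cc$y[a], cc$y[b], "-")^2))
  # identify groups by a known member cell (column-major linear indices)
  gid <- function(cell) which(vapply(all3$groups, function(g) cell %in% g,
                                     logical(1)))
  ga <- all3$groups[[gid((2 - 1) * 12 + 2)]]   # A at rows 2, cols 2:3
  gb <- all3$groups[[gid((6 - 1) * 12 + 2)]]   # B at rows 2, cols 6:7
  gc_ <- all3$groups[[gid((2 - 1) * 12 + 8)]]  # C at rows 8, cols 2:3
  expect_equal(dmin(ga, gb), 300)
  expect_gt(min(dmin(ga, gc_), dmin(gb, gc_)), 300)
  kept <- delineate_core_areas(g3, tau = 0.5, link_dist_m = 300)
  expect_equal(length(kept$groups), 2)    # the isolated group dropped
  merged <- delineate_core_areas(g3, tau = 0.5, link_dist_m = 300,
                                 isolated = "merge")
  expect_equal(length(merged$groups), 2)  # A+B merged, C its own node
  expect_equal(max(lengths(merged$groups)), 4)
})

test_that("lattice edges and conductances follow the mean-resistance rule", {
  # 1 x 2 raster, r = (1, 3): single edge with conductance 1/2
  r12 <- raster_grid(matrix(c(1, 3), 1, 2), res = 100)
  g12 <- build_lattice_graph(r12)
  expect_equal(nrow(g12$edges), 1)
  expect_equal(g12$edges$conductance, 0.5)
  # uniform 3 x 3 rook lattice: 12 edges of conductance 1
  g33 <- build_lattice_graph(raster_grid(matrix(1, 3, 3), res = 100),
                             neighbourhood = 4)
  expect_equal(nrow(g33$edges), 12)
  expect_true(all(g33$edges$conductance == 1))
  # random 4 x 4: edge list matches brute-force neighbour enumeration
  set.seed(8)
  rm <- matrix(runif(16, 0.5, 2), 4, 4)
  rm[2, 3] <- NA
  gg <- build_lattice_graph(raster_grid(rm, res = 100), neighbourhood = 8)
  want <- list()
  for (cell in which(is.finite(rm))) {
    r0 <- (cell - 1) %% 4 + 1; c0 <- (cell - 1) %/% 4 + 1
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      r1 <- r0 + di; c1 <- c0 + dj
      if (r1 < 1 || r1 > 4 || c1 < 1 || c1 > 4) next
      other <- (c1 - 1) * 4 + r1
      if (!is.finite(rm[other]) || other <= cell) next
      want[[length(want) + 1]] <- c(cell, other,
                                    1 / (sqrt(di^2 + dj^2) *
                                         (rm[cell] + rm[other]) / 2))
    }
  }
  want <- do.call(rbind, want)
  got <- cbind(pmin(gg$cells[gg$edges$a], gg$cells[gg$edges$b]),
               pmax(gg$cells[gg$edges$a], gg$cells[gg$edges$b]),
               gg$edges$conductance)
  ord <- function(m) m[order(m[, 1], m[, 2]), ]
  expect_equal(unname(ord(got)), unname(ord(want)), tolerance = 1e-12)
  expect_error(build_lattice_graph(raster_grid(matrix(-1, 2, 2))), "positive")
})

test_that("pair solves reproduce series closed forms exactly", {
  # 1 x 2, r = (1, 3): R_eff = mean resistance = 2; edge current 1
  r12 <- raster_grid(matrix(c(1, 3), 1, 2), res = 100)
  g <- build_lattice_graph(r12)
  sol <- solve_pair(g, source_cells = 1, target_cells = 2)
  expect_equal(sol$effective_resistance, 2.0, tolerance = 1e-12)
  expect_equal(sol$current[1, 1], 0.5, tolerance = 1e-12)  # half-sum at terminals
  # 1 x 3, r = (1, 2, 3): edges 1.5 + 2.5 in series -> R_eff = 4
  r13 <- raster_grid(matrix(c(1, 2, 3), 1, 3), res = 100)
  g3 <- build_lattice_graph(r13)
  sol3 <- solve_pair(g3, 1, 3)
  expect_equal(sol3$effective_resistance, 4.0, tolerance = 1e-12)
  expect_equal(sol3$current[1, 2], 1.0, tolerance = 1e-12)  # interior carries all
  # symmetry under source/target swap
  rev3 <- solve_pair(g3, 3, 1)
  expect_equal(rev3$effective_resistance, sol3$effective_resistance,
               tolerance = 1e-12)
  expect_error(solve_pair(g3, 1, 1), "overlap")
  expect_error(solve_pair(g3, integer(0), 2), "non-empty")
})

test_that("voltages match the dense pseudoinverse oracle on random grids", {
  set.seed(9)
  for (trial in 1:5) {
    nr <- sample(3:6, 1); nc <- sample(3:6, 1)
    rm <- matrix(exp(rnorm(nr * nc)), nr, nc)
    g <- build_lattice_graph(raster_grid(rm, res = 100))
    cells <- seq_len(nr * nc)
    st <- sample(cells, 2)
    sol <- solve_pair(g, st[1], st[2])
    ora <- dense_circuit_oracle(rm, st[1], st[2])
    expect_lt(abs(sol$effective_resistance - ora$effective_resistance), 1e-8)
    expect_lt(max(abs(sol$voltage[ora$cells] - ora$voltage)), 1e-8)
  }
})

test_that("Kirchhoff conservation and resistance scaling hold", {
  set.seed(10)
  rm <- matrix(exp(rnorm(36)), 6, 6)
  rg <- raster_grid(rm, res = 100)
  g <- build_lattice_graph(rg)
  sol <- solve_pair(g, 1, 36)
  # net current at every non-terminal node < 1e-9
  v <- sol$voltage[g$cells]
  net <- rep(0, length(g$cells))
  ie <- g$edges$conductance * (v[g$edges$a] - v[g$edges$b])
  for (k in seq_along(ie)) {
    net[g$edges$a[k]] <- net[g$edges$a[k]] - ie[k]
    net[g$edges$b[k]] <- net[g$edges$b[k]] + ie[k]
  }
  interior <- setdiff(seq_along(g$cells), match(c(1, 36), g$cells))
  expect_lt(max(abs(net[interior])), 1e-9)
  # flux across the source cut equals the unit injection
  expect_lt(abs(net[match(1, g$cells)] + 1), 1e-9)
  expect_lt(abs(net[match(36, g$cells)] - 1), 1e-9)
  # scaling all resistances by c scales R_eff by c, currents unchanged
  g2 <- build_lattice_graph(raster_grid(3.7 * rm, res = 100))
  sol2 <- solve_pair(g2, 1, 36)
  expect_equal(sol2$effective_resistance, 3.7 * sol$effective_resistance,
               tolerance = 1e-9)
  expect_lt(max(abs(sol2$current - sol$current), na.rm = TRUE), 1e-9)
  # effective resistance bounded above by the least-cost path resistance
  cd <- cost_distance(rg, 1, cell_size_m = 1)
  expect_lte(sol$effective_resistance, cd$values[6, 6] + 1e-9)
})

test_that("supernode collapse short-circuits multi-cell cores", {
  # two 2-cell cores at the ends of a uniform 1 x 6 strip
  r <- raster_grid(matrix(1, 1, 6), res = 100)
  g <- build_lattice_graph(r)
  sol <- solve_pair(g, c(1, 2), c(5, 6))
  # 3 series edges remain between the collapsed ends (2-3, 3-4, 4-5)
  expect_equal(sol$effective_resistance, 3.0, tolerance = 1e-12)
  expect_equal(sol$current[1, 3], 1.0, tolerance = 1e-12)
  # disconnected components: unreachable, infinite resistance, no crash
  rm <- matrix(1, 3, 5); rm[, 3] <- NA
  gd <- build_lattice_graph(raster_grid(rm, res = 100))
  sold <- solve_pair(gd, 1, 15)
  expect_false(sold$reachable)
  expect_equal(sold$effective_resistance, Inf)
  expect_true(all(sold$current == 0, na.rm = TRUE))
})

test_that("cumulative current sums pair solves and respects symmetry", {
  # two cores on a uniform 1 x 5 strip: every intermediate cell carries 1
  r <- raster_grid(matrix(1, 1, 5), res = 100)
  cores <- structure(list(groups = list(1L, 5L)), class = "CoreAreaSet")
  cm <- cumulative_current(r, cores)
  expect_equal(cm$current$values[1, 2:4], rep(1, 3), tolerance = 1e-9)
  expect_equal(cm$effective_resistance[1, 2], 4.0, tolerance = 1e-12)
  # additivity: pair currents summed independently equal the cumulative map
  ru <- raster_grid(matrix(1, 7, 7), res = 100)
  cores3 <- structure(list(groups = list(4L, 25L, 46L)), class = "CoreAreaSet")
  cm3 <- cumulative_current(ru, cores3)
  g <- build_lattice_graph(ru)
  manual <- matrix(0, 7, 7)
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    s <- solve_pair(g, cores3$groups[[p[1]]], cores3$groups[[p[2]]])
    cur <- s$current
    cur[c(cores3$groups[[p[1]]], cores3$groups[[p[2]]])] <- 0
    manual <- manual + cur
  }
  expect_equal(cm3$current$values, manual, tolerance = 1e-12)
  # three identical cores on a symmetric uniform grid: symmetric current map
  # (cores at cells (4,1), (4,4), (4,7) on the middle row)
  expect_lt(max(abs(cm3$current$values - cm3$current$values[, 7:1])), 1e-8)
  expect_error(cumulative_current(ru, structure(list(groups = list(1L)),
                                                class = "CoreAreaSet")),
               ">= 2")
})
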