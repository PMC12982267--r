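#' Polygon layers
#'
#' Planner corridors and pinch-point clusters are handled as simple polygon
#' layers: a `polygon_layer` is a list of polygons, each polygon a list of
#' rings (first ring the outer boundary, any further rings holes), each ring
#' an n x 2 coordinate matrix (open: last vertex is not repeated). All
#' coordinates live in the same projected planar CRS (metres) as the rasters.
#'
#' @param polygons list of polygons (each a list of rings).
#' @return object of class `polygon_layer`.
#' @export
polygon_layer <- function(polygons = list()) {
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, function(r) {
      r <- as.matrix(r)
      if (ncol(r) != 2) stop("rings must be n x 2 coordinate matrices")
      # drop a repeated closing vertex if present
      n <- nrow(r)
      if (n > 1 && all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]
      if (nrow(r) < 3) stop("rings need at least 3 distinct vertices")
      r
    })
  })
  structure(list(polygons = polygons), class = "polygon_layer")
}

#' @export
length.polygon_layer <- function(x) length(x$polygons)

#' @export
print.polygon_layer <- function(x, ...) {
  cat(sprintf("polygon_layer: %d polygons, total area %.4g m^2\n",
              length(x), layer_area(x)))
  invisible(x)
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Area of a polygon layer
#'
#' Sums signed areas polygon by polygon (outer ring minus holes) by the
#' shoelace formula. Overlapping polygons are double counted; use a
#' rasterisation count when a union area is needed.
#'
#' @param layer a `polygon_layer`.
#' @return area in m^2.
#' @export
layer_area <- function(layer) {
  sum(vapply(layer$polygons, function(p) {
    a <- ring_area(p[[1]])
    if (length(p) > 1)
      a <- a - sum(vapply(p[-1], ring_area, numeric(1)))
    a
  }, numeric(1)))
}

#' Point-in-layer test
#'
#' A point is inside the layer if it falls inside the outer ring of any
#' polygon and inside none of that polygon's holes. Points on an edge or
#' vertex count as inside.
#'
#' @param x,y point coordinates (m).
#' @param layer a `polygon_layer`.
#' @return logical vector.
#' @export
points_in_layer <- function(x, y, layer) {
  inside <- rep(FALSE, length(x))
  for (p in layer$polygons) {
    todo <- which(!inside)
    if (!length(todo)) break
    hit <- sp::point.in.polygon(x[todo], y[todo], p[[1]][, 1], p[[1]][, 2]) > 0
    if (length(p) > 1 && any(hit)) {
      for (h in p[-1]) {
        sub <- which(hit)
        inhole <- sp::point.in.polygon(x[todo][sub], y[todo][sub],
                                       h[, 1], h[, 2]) == 1
        hit[sub][inhole] <- FALSE
      }
    }
    inside[todo[hit]] <- TRUE
  }
  inside
}

circle_ring <- function(cx, cy, r, n = 32L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Buffer a point set by a radius (discretised)
#'
#' Returns the convex hull of vertices sampled on circles of radius
#' `buffer_m` around each point — the exact buffer of the convex hull of the
#' points, up to circle discretisation.
#'
#' @param xy n x 2 matrix of points.
#' @param buffer_m buffer radius (m).
#' @param n_arc vertices per circle.
#' @return one polygon (list of one ring).
#' @export
buffer_hull <- function(xy, buffer_m, n_arc = 32L) {
  xy <- as.matrix(xy)
  pts <- do.call(rbind, lapply(seq_len(nrow(xy)), function(i)
    circle_ring(xy[i, 1], xy[i, 2], buffer_m, n_arc)))
  list(pts[grDevices::chull(pts), , drop = FALSE])
}

#' Buffer a straight segment by a radius (capped rectangle)
#'
#' @param p1,p2 segment endpoints (length-2 numeric).
#' @param buffer_m half-width of the corridor (m); the polygon is
#'   `2 * buffer_m` wide with semicircular end caps.
#' @param n_arc vertices per semicircular cap (odd values include the cap
#'   apex, making the end extent exact).
#' @return one polygon (list of one ring).
#' @export
buffer_segment <- function(p1, p2, buffer_m, n_arc = 17L) {
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len == 0) return(list(circle_ring(p1[1], p1[2], buffer_m)))
  u <- d / len
  ang <- atan2(u[2], u[1])
  th1 <- ang + pi / 2 + seq(0, pi, length.out = n_arc)   # cap at p1
  th2 <- ang - pi / 2 + seq(0, pi, length.out = n_arc)   # cap at p2
  ring <- rbind(
    cbind(p1[1] + buffer_m * cos(th1), p1[2] + buffer_m * sin(th1)),
    cbind(p2[1] + buffer_m * cos(th2), p2[2] + buffer_m * sin(th2))
  )
  list(ring)
}

close_ring <- function(r) rbind(r, r[1, , drop = FALSE])

#' Write a polygon layer to GeoJSON
#'
#' One Feature per polygon; optional per-polygon properties.
#'
#' @param layer a `polygon_layer`.
#' @param path output path.
#' @param properties optional data.frame with one row per polygon.
#' @export
write_polygons <- function(layer, path, properties = NULL) {
  feats <- lapply(seq_along(layer$polygons), function(i) {
    p <- layer$polygons[[i]]
    coords <- lapply(p, function(r) {
      rc <- close_ring(r)
      lapply(seq_len(nrow(rc)), function(k) c(rc[k, 1], rc[k, 2]))
    })
    props <- if (is.null(properties)) stats::setNames(list(), character(0))
             else as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a polygon layer from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features; other geometry types are
#' rejected. Returns the layer plus any feature properties.
#'
#' @param path GeoJSON file path.
#' @return a `polygon_layer` with attribute `properties` (data.frame or NULL).
#' @export
read_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  polys <- list()
  props <- list()
  ring_from <- function(coords)
    do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
  for (f in gj$features) {
    g <- f$geometry
    if (g$type == "Polygon") {
      polys[[length(polys) + 1L]] <- lapply(g$coordinates, ring_from)
      props[[length(props) + 1L]] <- f$properties
    } else if (g$type == "MultiPolygon") {
      for (pc in g$coordinates) {
        polys[[length(polys) + 1L]] <- lapply(pc, ring_from)
        props[[length(props) + 1L]] <- f$properties
      }
    } else {
      stop(sprintf("unsupported geometry type '%s'", g$type))
    }
  }
  out <- polygon_layer(polys)
  if (any(lengths(props) > 0)) {
    attr(out, "properties") <-
      do.call(rbind, lapply(props, function(p)
        as.data.frame(lapply(p, function(v) if (is.null(v)) NA else v))))
  }
  out
}
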