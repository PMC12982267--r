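#' Aligned planar raster grid
#'
#' `raster_grid()` builds the light-weight raster container used throughout
#' the pipeline: a numeric matrix on a regular square-cell grid in a projected
#' planar coordinate system (metres). Rows run north to south (row 1 is the
#' top of the map), columns west to east, matching the row order of the ESRI
#' ASCII grid interchange format. Missing cells are `NA` (nodata).
#'
#' @param values numeric matrix of cell values; `NA` marks nodata.
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param res cell size in metres (square cells).
#' @return an object of class `RasterGrid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, res = 100) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(res) || length(res) != 1L || !is.finite(res) || res <= 0)
    stop("`res` must be a single positive number (metres)")
  storage.mode(values) <- "double"
  structure(
    list(values = values, xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         res = as.numeric(res)),
    class = "RasterGrid"
  )
}

#' @export
print.RasterGrid <- function(x, ...) {
  v <- x$values
  cat(sprintf("RasterGrid: %d rows x %d cols, res %g m\n", nrow(v), ncol(v), x$res))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$res, x$ymin, x$ymin + nrow(v) * x$res))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(fin), max(fin), sum(!is.finite(v))))
  invisible(x)
}

#' @export
dim.RasterGrid <- function(x) dim(x$values)

grid_nrow <- function(g) nrow(g$values)
grid_ncol <- function(g) ncol(g$values)

#' Cell-centre coordinates of every cell
#'
#' @param g a `RasterGrid`.
#' @return data.frame with columns `row`, `col`, `x`, `y` in matrix order
#'   (column-major, as `as.vector(g$values)`).
#' @export
cell_centres <- function(g) {
  nr <- grid_nrow(g); nc <- grid_ncol(g)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(
    row = row, col = col,
    x = g$xmin + (col - 0.5) * g$res,
    y = g$ymin + (nr - row + 0.5) * g$res
  )
}

#' Locate points on a grid
#'
#' @param g a `RasterGrid`.
#' @param x,y point coordinates (m).
#' @return data.frame with `row`, `col`, and `inside` (logical); `row`/`col`
#'   are `NA` for points outside the grid extent. Points exactly on the
#'   upper/right boundary are assigned to the last cell.
#' @export
grid_locate <- function(g, x, y) {
  nr <- grid_nrow(g); nc <- grid_ncol(g)
  col <- floor((x - g$xmin) / g$res) + 1L
  rowfb <- floor((y - g$ymin) / g$res) + 1L   # row counted from bottom
  col[x == g$xmin + nc * g$res] <- nc
  rowfb[y == g$ymin + nr * g$res] <- nr
  inside <- !is.na(col) & !is.na(rowfb) & col >= 1L & col <= nc & rowfb >= 1L & rowfb <= nr
  row <- nr - rowfb + 1L
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = row, col = col, inside = inside)
}

#' Extract cell values at point locations
#'
#' @inheritParams grid_locate
#' @return numeric vector; `NA` for points outside the grid or on nodata cells.
#' @export
extract_at <- function(g, x, y) {
  loc <- grid_locate(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- loc$inside
  out[ok] <- g$values[cbind(loc$row[ok], loc$col[ok])]
  out
}

#' Test whether two grids share the same geometry
#'
#' @param a,b `RasterGrid`s.
#' @param tol coordinate tolerance in metres.
#' @export
grids_aligned <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$res - b$res) < tol
}

stop_unless_aligned <- function(..., what = "rasters") {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!grids_aligned(gs[[1]], gs[[i]]))
      stop(sprintf("%s are not aligned on the same grid", what))
  invisible(TRUE)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' ESRI ASCII (.asc) is a plain-text raster interchange format readable by
#' standard GIS tools (GDAL, QGIS, ArcGIS). Values are written row by row
#' from the top of the map; nodata cells are written as the `nodata` sentinel.
#'
#' @param g a `RasterGrid`.
#' @param path output file path.
#' @param nodata sentinel value used for `NA` cells.
#' @param digits significant digits written (default 15, round-trip safe for
#'   doubles in practice at the precisions used here).
#' @export
write_raster <- function(g, path, nodata = -9999, digits = 15) {
  v <- g$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10f", g$xmin),
    sprintf("yllcorner %.10f", g$ymin),
    sprintf("cellsize %.10f", g$res),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1, function(r) {
    r[!is.finite(r)] <- nodata
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a raster from an ESRI ASCII grid file
#'
#' @param path file path to a .asc raster.
#' @return a `RasterGrid`; nodata cells become `NA`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields")
  if (!is.null(hdr$xllcenter) || !is.null(hdr$yllcenter))
    stop("cell-centre referenced .asc files are not supported; use llcorner")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, xmin = hdr$xllcorner %||% 0, ymin = hdr$yllcorner %||% 0,
              res = hdr$cellsize)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Min-max rescale a raster to [0, 1] over valid cells
#'
#' @param g a `RasterGrid`.
#' @export
rescale01 <- function(g) {
  v <- g$values
  fin <- is.finite(v)
  rng <- range(v[fin])
  if (diff(rng) == 0) stop("cannot rescale a constant raster to [0, 1]")
  g$values <- (v - rng[1]) / diff(rng)
  g
}
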