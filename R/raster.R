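#' Regular raster grid of elevations or heights
#'
#' Lightweight container for DTM/DSM/CHM layers. The grid origin is the
#' lower-left corner of the lower-left cell, cells are half-open
#' `[x0 + i*res, x0 + (i+1)*res)`, and `values` is a matrix with one row per
#' y-index (row 1 = southernmost row) and one column per x-index. Cell centers
#' are at `x0 + (col - 0.5) * res`, `y0 + (row - 0.5) * res`. Missing cells
#' are `NA`.
#'
#' @param values numeric matrix of cell values (rows = y from south to north).
#' @param x0,y0 coordinates of the lower-left corner (m).
#' @param res cell size (m), > 0.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, x0, y0, res) {
  stopifnot(is.matrix(values), is.numeric(res), length(res) == 1L)
  if (res <= 0) stop("raster resolution must be > 0")
  structure(list(values = values, x0 = x0, y0 = y0, res = res),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, res %.3g m, origin (%.2f, %.2f)\n",
              nrow(x$values), ncol(x$values), x$res, x$x0, x$y0))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: min %.3f, mean %.3f, max %.3f (%d NA)\n",
                min(v), mean(v), max(v), sum(!is.finite(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

# x/y coordinates of all cell centers, recycled in matrix layout
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  list(x = grid$x0 + (seq_len(nc) - 0.5) * grid$res,
       y = grid$y0 + (seq_len(nr) - 0.5) * grid$res)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$x0 - b$x0) < tol && abs(a$y0 - b$y0) < tol &&
    abs(a$res - b$res) < tol
}

geometry_string <- function(g) {
  sprintf("[%d x %d @ %.3g m, origin (%.3f, %.3f)]",
          nrow(g$values), ncol(g$values), g$res, g$x0, g$y0)
}

# row/col indices (1-based, row 1 = south) of points; points on the far
# north/east edge are clamped into the last cell so a cloud's bounding box
# maps onto the grid built from it.
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$x0) / grid$res) + 1L
  row <- floor((y - grid$y0) / grid$res) + 1L
  col <- pmin.int(pmax.int(col, 1L), ncol(grid$values))
  row <- pmin.int(pmax.int(row, 1L), nrow(grid$values))
  list(row = as.integer(row), col = as.integer(col))
}

# empty grid covering the given extent
empty_grid <- function(xmin, xmax, ymin, ymax, res) {
  nc <- max(1L, as.integer(ceiling((xmax - xmin) / res)))
  nr <- max(1L, as.integer(ceiling((ymax - ymin) / res)))
  raster_grid(matrix(NA_real_, nr, nc), xmin, ymin, res)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Plain-text `.asc` format: a six-line header followed by rows of cell
#' values, northernmost row first. `NA` cells are written as the nodata
#' sentinel.
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[!is.finite(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$x0),
    sprintf("yllcorner %.10g", grid$y0),
    sprintf("cellsize %.10g", grid$res),
    sprintf("NODATA_value %.10g", nodata)), con)
  # ESRI order: top row first
  utils::write.table(v[rev(seq_len(nrow(v))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path file written by [write_ascii_grid()] or any GIS.
#' @return a [raster_grid()]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA_real_
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  raster_grid(v, val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]])
}
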