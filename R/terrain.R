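# Ground classification and raster construction. The ground filter is a
# simplified cloth simulation: the cloud is inverted in z, a grid of cloth
# particles is dropped under gravity onto the inverted surface, neighbour
# springs smooth the cloth, and points within `threshold` of the settled
# cloth are labelled ground.

# lower-left-origin grid covering an extent
grid_from_extent <- function(extent, res) {
  empty_grid(extent[1], extent[2], extent[3], extent[4], res)
}

cloud_extent <- function(cloud) {
  c(min(cloud$x), max(cloud$x), min(cloud$y), max(cloud$y))
}

resolve_grid <- function(cloud, grid, res, extent) {
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "raster_grid"))
    return(raster_grid(matrix(NA_real_, nrow(grid$values), ncol(grid$values)),
                       grid$x0, grid$y0, grid$res))
  }
  if (is.null(extent)) extent <- cloud_extent(cloud)
  grid_from_extent(extent, res)
}

# max per group of a numeric vector, groups given as integer cell ids
group_max <- function(idx, z, ncell) {
  o <- order(idx, z)
  last <- !duplicated(idx[o], fromLast = TRUE)
  out <- rep(NA_real_, ncell)
  out[idx[o][last]] <- z[o][last]
  out
}

# bilinear interpolation of a grid at arbitrary coordinates (values indexed
# at cell centers; queries outside the center lattice are clamped to it)
bilinear <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  gx <- (x - grid$x0) / grid$res - 0.5
  gy <- (y - grid$y0) / grid$res - 0.5
  gx <- pmin(pmax(gx, 0), nc - 1)
  gy <- pmin(pmax(gy, 0), nr - 1)
  c0 <- pmin(floor(gx), nc - 2); c0 <- pmax(c0, 0)
  r0 <- pmin(floor(gy), nr - 2); r0 <- pmax(r0, 0)
  if (nc == 1L) { c0 <- rep(0, length(x)); tx <- rep(0, length(x)) }
  else tx <- gx - c0
  if (nr == 1L) { r0 <- rep(0, length(y)); ty <- rep(0, length(y)) }
  else ty <- gy - r0
  v <- grid$values
  i00 <- r0 + 1 + c0 * nr
  i10 <- i00 + if (nr > 1L) 1 else 0
  i01 <- i00 + if (nc > 1L) nr else 0
  i11 <- i01 + if (nr > 1L) 1 else 0
  (1 - tx) * (1 - ty) * v[i00] + (1 - tx) * ty * v[i10] +
    tx * (1 - ty) * v[i01] + tx * ty * v[i11]
}

# fill NA cells of a grid by KNN-IDW from the non-NA cell centers
fill_na_cells <- function(grid, k = 10, power = 2) {
  v <- grid$values
  na <- which(!is.finite(v))
  if (!length(na)) return(grid)
  ok <- which(is.finite(v))
  if (!length(ok)) stop("cannot fill a raster with no finite cells")
  nr <- nrow(v)
  ctr <- cell_centers(grid)
  px <- ctr$x[(ok - 1L) %/% nr + 1L]; py <- ctr$y[(ok - 1L) %% nr + 1L]
  qx <- ctr$x[(na - 1L) %/% nr + 1L]; qy <- ctr$y[(na - 1L) %% nr + 1L]
  v[na] <- knn_idw_cpp(px, py, v[ok], qx, qy,
                       as.integer(min(k, length(ok))), power)
  grid$values <- v
  grid
}

#' Classify ground points with a cloth-simulation filter
#'
#' The cloud is inverted in z and a rigid cloth is dropped onto it from
#' above: per cloth cell the highest inverted point is the stopping surface,
#' gravity lowers unpinned particles each iteration, and `rigidness` rounds
#' of neighbour-averaging per iteration act as the internal springs. Points
#' within `threshold` (metres) of the settled cloth are labelled `"ground"`.
#' Cloth cells containing no points take an inverse-distance-interpolated
#' stopping surface so the cloth cannot sag through unsampled gaps.
#'
#' @param cloud a [point_cloud()], non-empty.
#' @param cloth_resolution cloth particle spacing (m).
#' @param rigidness integer >= 1; smoothing passes per gravity step (stiffer
#'   cloth bridges canopy gaps more).
#' @param threshold classification distance to the settled cloth (m).
#' @param max_iter gravity iteration cap.
#' @return the cloud with a `label` column (`"ground"` / `"non-ground"`).
#' @export
classify_ground <- function(cloud, cloth_resolution = 0.5, rigidness = 2,
                            threshold = 0.5, max_iter = 500L) {
  if (nrow(cloud) == 0L) stop("cannot classify an empty point cloud")
  zi <- -cloud$z
  ext <- cloud_extent(cloud)
  grid <- grid_from_extent(ext + c(-1, 1, -1, 1) * cloth_resolution / 2,
                           cloth_resolution)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  ci <- cell_index(grid, cloud$x, cloud$y)
  idx <- ci$row + (ci$col - 1L) * nr
  hp <- matrix(group_max(idx, zi, nr * nc), nr, nc)
  grid$values <- hp
  hp <- fill_na_cells(grid)$values

  g <- 0.2 * max(cloth_resolution, 0.5)   # gravity displacement per step (m)
  cloth <- matrix(max(hp) + 1, nr, nc)
  pinned <- matrix(FALSE, nr, nc)
  navg <- function(m) {                   # 4-neighbour mean with edge padding
    up <- rbind(m[1, , drop = FALSE], m[-nr, , drop = FALSE])
    dn <- rbind(m[-1, , drop = FALSE], m[nr, , drop = FALSE])
    lf <- cbind(m[, 1, drop = FALSE], m[, -nc, drop = FALSE])
    rt <- cbind(m[, -1, drop = FALSE], m[, nc, drop = FALSE])
    (up + dn + lf + rt) / 4
  }
  for (it in seq_len(max_iter)) {
    prev <- cloth
    cloth[!pinned] <- cloth[!pinned] - g
    hit <- !pinned & cloth <= hp
    cloth[hit] <- hp[hit]; pinned[hit] <- TRUE
    for (r in seq_len(rigidness)) {
      sm <- navg(cloth)
      cloth[!pinned] <- cloth[!pinned] + 0.5 * (sm[!pinned] - cloth[!pinned])
      hit <- !pinned & cloth <= hp
      cloth[hit] <- hp[hit]; pinned[hit] <- TRUE
    }
    if (all(pinned) || max(abs(cloth - prev)) < 1e-6) break
  }
  grid$values <- cloth
  dist <- abs(bilinear(grid, cloud$x, cloud$y) - zi)
  cloud$label <- ifelse(dist <= threshold, "ground", "non-ground")
  class(cloud) <- c("point_cloud", "data.frame")
  cloud
}

#' Interpolate a digital terrain model from ground points
#'
#' Every cell value is the inverse-distance-weighted mean of the `k` nearest
#' ground points (weights `d^-power`, distances from the cell center). A cell
#' center coincident with a ground point takes that point's elevation
#' exactly.
#'
#' @param cloud a [point_cloud()]; if it carries labels only `"ground"`
#'   points are used, otherwise all points are treated as ground.
#' @param res cell size (m), default 0.5.
#' @param k number of neighbours (default 10).
#' @param power inverse-distance exponent (default 2).
#' @param grid optional [raster_grid()] template fixing the geometry.
#' @param extent optional `c(xmin, xmax, ymin, ymax)` when `grid` is absent.
#' @return a [raster_grid()] DTM.
#' @export
interpolate_dtm <- function(cloud, res = 0.5, k = 10, power = 2,
                            grid = NULL, extent = NULL) {
  if (nrow(cloud) == 0L) stop("cannot interpolate from an empty point cloud")
  g <- if (!is.null(cloud$label)) cloud[cloud$label == "ground", ] else cloud
  if (nrow(g) < k)
    stop(sprintf(paste("only %d ground points but k = %d;",
                       "use a smaller k"), nrow(g), k))
  out <- resolve_grid(cloud, grid, res, extent)
  ctr <- cell_centers(out)
  nr <- nrow(out$values)
  qx <- rep(ctr$x, each = nr)
  qy <- rep(ctr$y, times = ncol(out$values))
  out$values <- matrix(knn_idw_cpp(g$x, g$y, g$z, qx, qy,
                                   as.integer(k), power),
                       nr, ncol(out$values))
  out
}

#' Rasterize a digital surface model (highest point per cell)
#'
#' Each cell takes the maximum z of the points falling in it (half-open
#' cells); empty cells are filled by KNN-IDW from the non-empty cell centers.
#'
#' @inheritParams interpolate_dtm
#' @param fill_k,fill_power KNN-IDW parameters for empty-cell filling.
#' @return a [raster_grid()] DSM.
#' @export
build_dsm <- function(cloud, res = 0.5, grid = NULL, extent = NULL,
                      fill_k = 10, fill_power = 2) {
  if (nrow(cloud) == 0L) stop("cannot rasterize an empty point cloud")
  out <- resolve_grid(cloud, grid, res, extent)
  nr <- nrow(out$values)
  ci <- cell_index(out, cloud$x, cloud$y)
  idx <- ci$row + (ci$col - 1L) * nr
  out$values <- matrix(group_max(idx, cloud$z, nr * ncol(out$values)),
                       nr, ncol(out$values))
  fill_na_cells(out, k = fill_k, power = fill_power)
}

#' Canopy height model: DSM minus DTM
#'
#' Cellwise subtraction on identical geometries; negative heights (ground
#' noise dipping below the interpolated terrain) are clamped to zero since
#' vegetation cannot be below ground.
#'
#' @param dsm,dtm [raster_grid()]s with identical geometry.
#' @return a [raster_grid()] CHM with all values >= 0.
#' @export
build_chm <- function(dsm, dtm) {
  if (!same_geometry(dsm, dtm))
    stop("DSM and DTM geometries differ: DSM ", geometry_string(dsm),
         " vs DTM ", geometry_string(dtm))
  out <- dsm
  out$values <- pmax(dsm$values - dtm$values, 0)
  out
}
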