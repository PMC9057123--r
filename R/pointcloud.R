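#' Construct a 3D point cloud
#'
#' A point cloud is a data frame with numeric columns `x`, `y`, `z`
#' (metres) and, after ground classification, a `label` column with values
#' `"ground"` / `"non-ground"`.
#'
#' @param x,y,z numeric coordinate vectors of equal length (m).
#' @param label optional character vector of per-point labels.
#' @return an object of class `point_cloud` (also a `data.frame`).
#' @export
point_cloud <- function(x, y, z, label = NULL) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  if (length(x) && !all(is.finite(x) & is.finite(y) & is.finite(z)))
    stop("point cloud coordinates must be finite")
  d <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!is.null(label)) {
    stopifnot(length(label) == length(x),
              all(label %in% c("ground", "non-ground")))
    d$label <- label
  }
  class(d) <- c("point_cloud", "data.frame")
  d
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points", nrow(x)))
  if (nrow(x))
    cat(sprintf(", extent x [%.2f, %.2f] y [%.2f, %.2f] z [%.2f, %.2f]",
                min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  if (!is.null(x$label))
    cat(sprintf(", %d ground / %d non-ground",
                sum(x$label == "ground"), sum(x$label != "ground")))
  cat("\n")
  invisible(x)
}

#' Read and write point clouds as XYZ CSV
#'
#' Plain-text exchange format: a CSV with header columns `x,y,z` (metres).
#' A `label` column, when present, survives the round trip.
#'
#' @param cloud a [point_cloud()].
#' @param path file path.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` returns a
#'   [point_cloud()].
#' @export
write_xyz <- function(cloud, path) {
  d <- as.data.frame(cloud)
  # mm precision, matching the LAS coordinate quantisation
  d$x <- round(d$x, 3); d$y <- round(d$y, 3); d$z <- round(d$z, 3)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(d)))
    stop("XYZ CSV must have columns x, y, z: ", path)
  point_cloud(d$x, d$y, d$z, label = d$label)
}

# --- minimal LAS 1.2 / point data record format 0 -------------------------
# Only the fields this pipeline uses are honoured: coordinates (scaled
# int32) and the ASPRS classification byte (2 = ground, 1 = unclassified).
# Coordinates are stored at 1 mm resolution.

LAS_HEADER_SIZE <- 227L
LAS_RECORD_SIZE <- 20L

#' Write a point cloud to a LAS file (version 1.2, point format 0)
#'
#' @param cloud a [point_cloud()]; a `label` column is stored in the ASPRS
#'   classification byte (ground = 2, non-ground = 1).
#' @param path output file path.
#' @param scale coordinate quantisation step in metres (default 1 mm).
#' @return `path`, invisibly.
#' @export
write_las <- function(cloud, path, scale = 0.001) {
  n <- nrow(cloud)
  if (n == 0L) stop("cannot write an empty point cloud to LAS")
  off <- c(min(cloud$x), min(cloud$y), min(cloud$z))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, 4L, eos = NULL)
  writeBin(rep(0L, 2L), con, size = 2)            # source id, global encoding
  writeBin(raw(16L), con)                          # GUID
  writeBin(c(1L, 2L), con, size = 1)               # version 1.2
  writeChar(formatC("canopygain", width = 32L), con, 32L, eos = NULL)
  writeChar(formatC("canopygain", width = 32L), con, 32L, eos = NULL)
  writeBin(c(1L, 2026L), con, size = 2)            # day, year
  writeBin(LAS_HEADER_SIZE, con, size = 2)
  writeBin(LAS_HEADER_SIZE, con, size = 4)         # offset to point data
  writeBin(0L, con, size = 4)                      # number of VLRs
  writeBin(0L, con, size = 1)                      # point data format 0
  writeBin(LAS_RECORD_SIZE, con, size = 2)
  writeBin(n, con, size = 4)
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4)    # points by return
  writeBin(rep(scale, 3), con, size = 8)
  writeBin(off, con, size = 8)
  writeBin(c(max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
             max(cloud$z), min(cloud$z)), con, size = 8)

  block <- matrix(as.raw(0L), LAS_RECORD_SIZE, n)
  block[1:4, ]  <- matrix(writeBin(as.integer(round((cloud$x - off[1]) / scale)),
                                   raw(), size = 4), 4L)
  block[5:8, ]  <- matrix(writeBin(as.integer(round((cloud$y - off[2]) / scale)),
                                   raw(), size = 4), 4L)
  block[9:12, ] <- matrix(writeBin(as.integer(round((cloud$z - off[3]) / scale)),
                                   raw(), size = 4), 4L)
  block[15, ] <- as.raw(9L)                        # return 1 of 1
  cls <- if (is.null(cloud$label)) rep(0L, n) else
    ifelse(cloud$label == "ground", 2L, 1L)
  block[16, ] <- as.raw(cls)
  writeBin(as.vector(block), con)
  invisible(path)
}

#' Read a LAS file (point formats 0-3, coordinates and classification only)
#'
#' @param path LAS file path.
#' @return a [point_cloud()]; ASPRS class 2 becomes `"ground"`, any other
#'   nonzero class `"non-ground"`; files with all-zero classification get no
#'   label column.
#' @export
read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path)
  seek(con, 96L)
  data_offset <- readBin(con, "integer", size = 4)
  readBin(con, "integer", size = 4)                # n VLRs
  readBin(con, "integer", size = 1)                # point format
  rec_len <- readBin(con, "integer", size = 2)
  n <- readBin(con, "integer", size = 4)
  seek(con, 131L)
  scl <- readBin(con, "double", n = 3L, size = 8)
  off <- readBin(con, "double", n = 3L, size = 8)
  seek(con, data_offset)
  block <- matrix(readBin(con, "raw", n = n * rec_len), rec_len, n)
  xi <- readBin(as.vector(block[1:4, ]), "integer", n = n, size = 4)
  yi <- readBin(as.vector(block[5:8, ]), "integer", n = n, size = 4)
  zi <- readBin(as.vector(block[9:12, ]), "integer", n = n, size = 4)
  cls <- as.integer(block[16, ])
  label <- if (all(cls == 0L)) NULL else
    ifelse(cls == 2L, "ground", "non-ground")
  point_cloud(xi * scl[1] + off[1], yi * scl[2] + off[2], zi * scl[3] + off[3],
              label = label)
}
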