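# Treetop detection by variable-radius local maxima on the CHM and crown
# delineation by seeded region growing, following the individual-tree
# workflow standard in drone forestry (local-maximum filter + dalponte-style
# growing), with per-tree height and convex-hull crown area extraction.

#' Variable moving-window radius for treetop detection
#'
#' The search radius grows linearly with tree height:
#' `radius = H * 0.05 + 2.6` metres, so taller trees — which cast wider
#' crowns — suppress spurious maxima over a wider neighbourhood.
#'
#' @param H tree height (m), >= 0; vectorised.
#' @return window radius in metres.
#' @export
variable_window_radius <- function(H) {
  if (any(H < 0)) stop("tree height must be >= 0")
  H * 0.05 + 2.6
}

# cache of window offsets: cell-offset matrix for a radius given in cells
window_offsets <- function(rad_cells) {
  r <- ceiling(rad_cells)
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- (dr * dr + dc * dc) <= rad_cells * rad_cells &
    !(dr == 0 & dc == 0)
  cbind(dr[keep], dc[keep])
}

#' Detect treetops on a canopy height model
#'
#' A cell is a treetop iff its height is at least `min_height` and strictly
#' greater than every other cell whose center lies within
#' [variable_window_radius()] of it (the radius is evaluated at the cell's
#' own height). On exact plateaus the cell with the lowest (row, col) index
#' wins. Tops are returned sorted by descending height, then index.
#'
#' @param chm a [raster_grid()] canopy height model.
#' @param min_height minimum tree height (m), default 2.6.
#' @return a data frame of class `treetops`: `tree_id, x, y, H, row, col`.
#' @export
detect_treetops <- function(chm, min_height = 2.6) {
  v <- chm$values
  nr <- nrow(v); nc <- ncol(v)
  cand <- which(is.finite(v) & v >= min_height)
  if (!length(cand)) {
    out <- data.frame(tree_id = integer(), x = numeric(), y = numeric(),
                      H = numeric(), row = integer(), col = integer())
    class(out) <- c("treetops", "data.frame")
    return(out)
  }
  crow <- (cand - 1L) %% nr + 1L
  ccol <- (cand - 1L) %/% nr + 1L
  offs_cache <- new.env(parent = emptyenv())
  is_top <- logical(length(cand))
  for (i in seq_along(cand)) {
    h <- v[cand[i]]
    rad_cells <- variable_window_radius(h) / chm$res
    key <- sprintf("%.6f", rad_cells)
    offs <- offs_cache[[key]]
    if (is.null(offs)) offs_cache[[key]] <- offs <- window_offsets(rad_cells)
    rr <- crow[i] + offs[, 1]; cc <- ccol[i] + offs[, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nb <- v[rr[ok] + (cc[ok] - 1L) * nr]
    nb <- nb[is.finite(nb)]
    if (!length(nb) || h > max(nb)) { is_top[i] <- TRUE; next }
    if (h < max(nb)) next
    # plateau: win only against equal-height cells with a higher index
    eq <- which(nb == h)
    rre <- rr[ok][eq]; cce <- cc[ok][eq]
    is_top[i] <- all(cce > ccol[i] | (cce == ccol[i] & rre > crow[i]))
  }
  sel <- which(is_top)
  o <- sel[order(-v[cand[sel]], cand[sel])]
  out <- data.frame(
    tree_id = seq_along(o),
    x = chm$x0 + (ccol[o] - 0.5) * chm$res,
    y = chm$y0 + (crow[o] - 0.5) * chm$res,
    H = v[cand[o]], row = crow[o], col = ccol[o])
  class(out) <- c("treetops", "data.frame")
  out
}

#' Delineate crowns by seeded region growing
#'
#' Starting from each treetop, a 4-neighbour cell joins the crown when its
#' height exceeds `seed_frac` times the seed height and `crown_frac` times
#' the current region mean, lies within `max_crown_diameter / 2` of the seed,
#' and is at least `min_height`. Cells reachable from two crowns in the same
#' growth round go to the nearer seed (ties to the taller, then
#' lower-indexed, seed). Growth order does not depend on the order of `tops`.
#'
#' @param chm a [raster_grid()] canopy height model.
#' @param tops treetops from [detect_treetops()].
#' @param seed_frac,crown_frac growing thresholds in (0, 1); defaults 0.45
#'   and 0.55.
#' @param max_crown_diameter largest allowed crown diameter (m), default 5.
#' @param min_height minimum canopy height for crown membership (m).
#' @return an object of class `crown_segments`: a list with `segments` (one
#'   list per tree: `tree_id`, `cells` (row/col matrix), `seed`, `n_cells`)
#'   and `assignment` (a [raster_grid()] of tree ids, 0 = unassigned).
#' @export
segment_crowns <- function(chm, tops, seed_frac = 0.45, crown_frac = 0.55,
                           max_crown_diameter = 5, min_height = 2.6) {
  stopifnot(nrow(tops) > 0, seed_frac > 0, seed_frac < 1,
            crown_frac > 0, crown_frac < 1)
  v <- chm$values
  nr <- nrow(v); nc <- ncol(v)
  seed_idx <- tops$row + (tops$col - 1L) * nr
  if (anyDuplicated(seed_idx))
    stop("two treetops occupy the same CHM cell; tops must be distinct")
  # canonical processing order: tallest seed first, then index
  ord <- order(-tops$H, seed_idx)
  seedH <- tops$H[ord]
  srow <- tops$row[ord]; scol <- tops$col[ord]
  ids <- tops$tree_id[ord]
  k <- length(ord)

  assign_m <- matrix(0L, nr, nc)
  assign_m[srow + (scol - 1L) * nr] <- seq_len(k)
  reg_sum <- seedH; reg_n <- rep(1L, k)
  frontier <- lapply(seq_len(k), function(i) cbind(srow[i], scol[i]))
  maxr2 <- (max_crown_diameter / 2 / chm$res)^2
  dnb <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))

  repeat {
    # gather candidate claims from every region's frontier
    claims <- vector("list", k)
    for (i in seq_len(k)) {
      fr <- frontier[[i]]
      if (is.null(fr) || nrow(fr) == 0L) next
      rr <- rep(fr[, 1], each = 4L) + rep(dnb[, 1], nrow(fr))
      cc <- rep(fr[, 2], each = 4L) + rep(dnb[, 2], nrow(fr))
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      rr <- rr[ok]; cc <- cc[ok]
      idx <- rr + (cc - 1L) * nr
      d2 <- (rr - srow[i])^2 + (cc - scol[i])^2
      h <- v[idx]
      keep <- assign_m[idx] == 0L & is.finite(h) & h >= min_height &
        h > seed_frac * seedH[i] & h > crown_frac * (reg_sum[i] / reg_n[i]) &
        d2 <= maxr2
      if (!any(keep)) next
      claims[[i]] <- data.frame(idx = idx[keep], row = rr[keep],
                                col = cc[keep], region = i, d2 = d2[keep])
    }
    cl <- do.call(rbind, claims)
    if (is.null(cl) || nrow(cl) == 0L) break
    # contested cells go to the nearer seed; ties to the taller/earlier seed
    o <- order(cl$idx, cl$d2, cl$region)
    cl <- cl[o, ]
    cl <- cl[!duplicated(cl$idx), ]
    assign_m[cl$idx] <- cl$region
    newf <- split(seq_len(nrow(cl)), cl$region)
    frontier <- lapply(seq_len(k), function(i) NULL)
    for (rg in names(newf)) {
      i <- as.integer(rg)
      sel <- newf[[rg]]
      frontier[[i]] <- cbind(cl$row[sel], cl$col[sel])
      reg_sum[i] <- reg_sum[i] + sum(v[cl$idx[sel]])
      reg_n[i] <- reg_n[i] + length(sel)
    }
  }

  segments <- lapply(seq_len(k), function(i) {
    cells <- which(assign_m == i)
    list(tree_id = ids[i],
         cells = cbind(row = (cells - 1L) %% nr + 1L,
                       col = (cells - 1L) %/% nr + 1L),
         seed = c(row = srow[i], col = scol[i]),
         n_cells = length(cells))
  })
  segments <- segments[order(ids)]
  ar <- raster_grid(assign_m * 1.0, chm$x0, chm$y0, chm$res)
  # relabel assignment raster with tree ids
  ar$values[assign_m > 0] <- ids[assign_m[assign_m > 0]]
  structure(list(segments = segments, assignment = ar),
            class = "crown_segments")
}

#' @export
print.crown_segments <- function(x, ...) {
  n <- vapply(x$segments, `[[`, 0L, "n_cells")
  cat(sprintf("crown_segments: %d crowns, %d-%d cells each (median %.0f)\n",
              length(n), min(n), max(n), stats::median(n)))
  invisible(x)
}

# polygon area by the shoelace formula (vertices in order)
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Per-tree height and crown area from crown segments
#'
#' Height is the maximum CHM value over the crown's cells; crown area is the
#' area of the 2D convex hull of the member cell centers (shoelace formula).
#' Degenerate crowns (< 3 non-collinear cells) fall back to
#' `n_cells * resolution^2` with a warning.
#'
#' @param segments a [segment_crowns()] result.
#' @param chm the CHM the segments were grown on.
#' @return a data frame: `tree_id, x, y, H, CA, n_cells`, with the hulls in
#'   attribute `"hulls"` (list of two-column vertex matrices, metres).
#' @export
crown_metrics <- function(segments, chm) {
  v <- chm$values; nr <- nrow(v)
  res <- chm$res
  hulls <- list()
  rows <- lapply(segments$segments, function(s) {
    cells <- s$cells
    cx <- chm$x0 + (cells[, "col"] - 0.5) * res
    cy <- chm$y0 + (cells[, "row"] - 0.5) * res
    h <- max(v[cells[, "row"] + (cells[, "col"] - 1L) * nr])
    hull_i <- grDevices::chull(cx, cy)
    ca <- if (length(hull_i) >= 3)
      shoelace_area(cx[hull_i], cy[hull_i]) else 0
    if (ca <= 0) {
      warning(sprintf("crown %d is degenerate (%d cells); using cell area",
                      s$tree_id, nrow(cells)))
      ca <- nrow(cells) * res^2
    }
    hulls[[as.character(s$tree_id)]] <<- cbind(x = cx[hull_i], y = cy[hull_i])
    data.frame(tree_id = s$tree_id,
               x = chm$x0 + (s$seed["col"] - 0.5) * res,
               y = chm$y0 + (s$seed["row"] - 0.5) * res,
               H = h, CA = ca, n_cells = nrow(cells))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "hulls") <- hulls
  out
}

#' Match detected trees to planted trial positions
#'
#' Each detected top is matched to the nearest planted position within
#' `max_dist` metres; unmatched detections are dropped with their count
#' reported, and a planted tree claims at most one detection (nearest wins).
#'
#' @param metrics output of [crown_metrics()] (or any table with
#'   `tree_id, x, y`).
#' @param trees a `true_trees` table from [simulate_trial()] or a trial
#'   design table with `tree_id, site, block, family, x, y`.
#' @param max_dist matching radius (m), default 1.5.
#' @return `metrics` with `site, block, family` and the planted `tree_id`
#'   (column `planted_id`) appended; unmatched rows removed.
#' @export
match_treetops <- function(metrics, trees, max_dist = 1.5) {
  if (!nrow(metrics)) stop("no detected trees to match")
  d2 <- outer(metrics$x, trees$x, "-")^2 + outer(metrics$y, trees$y, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(nrow(metrics)), nearest)])
  ok <- dist <= max_dist
  # one detection per planted tree: keep the nearest
  o <- order(nearest[ok], dist[ok])
  keep_rows <- which(ok)[o]
  keep_rows <- keep_rows[!duplicated(nearest[keep_rows])]
  out <- metrics[sort(keep_rows), , drop = FALSE]
  m <- nearest[sort(keep_rows)]
  out$planted_id <- trees$tree_id[m]
  out$site <- trees$site[m]
  out$block <- trees$block[m]
  out$family <- trees$family[m]
  n_drop <- nrow(metrics) - nrow(out)
  if (n_drop > 0)
    message(sprintf("%d detection(s) unmatched within %.2f m", n_drop,
                    max_dist))
  rownames(out) <- NULL
  out
}

#' Write crown polygons to GeoJSON
#'
#' @param metrics output of [crown_metrics()] (carries the hulls).
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_crowns_geojson <- function(metrics, path) {
  hulls <- attr(metrics, "hulls")
  feats <- lapply(seq_len(nrow(metrics)), function(i) {
    hv <- hulls[[as.character(metrics$tree_id[i])]]
    ring <- rbind(hv, hv[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(tree_id = metrics$tree_id[i],
                           H_m = metrics$H[i], CA_m2 = metrics$CA[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(j) c(ring[j, 1], ring[j, 2]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
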