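test_that("the variable window radius is linear in height", {
  expect_identical(variable_window_radius(0), 2.6)
  expect_equal(variable_window_radius(8), 3.0)
  expect_equal(variable_window_radius(2.6), 2.73)
  H <- seq(0.5, 40, by = 0.5)
  expect_equal((variable_window_radius(H) - 2.6) / H, rep(0.05, length(H)),
               tolerance = 1e-12)
  expect_error(variable_window_radius(-1), ">= 0")
})

test_that("a CHM entirely below the height threshold yields no treetops", {
  chm <- raster_grid(matrix(runif(400, 0, 2.5), 20, 20), 0, 0, 0.5)
  expect_identical(nrow(detect_treetops(chm)), 0L)
})

test_that("isolated cones yield one treetop each at the apex height", {
  chm <- cone_chm(apexes = rbind(c(5, 10), c(11, 10)), H = c(8, 8),
                  rb = 1.5, res = 0.5)
  tops <- detect_treetops(chm)
  # apexes 6 m apart, window radius 3.0 m at H = 8: both survive
  expect_identical(nrow(tops), 2L)
  expect_equal(sort(tops$x), c(4.75, 10.75), tolerance = 0.5)
  expect_true(all(abs(tops$H - 8) < 8 / 1.5 * 0.5))  # half-cell cone slope
})

test_that("close cones suppress each other within the window radius", {
  chm <- cone_chm(apexes = rbind(c(8, 10), c(10, 10)), H = c(8, 7.5),
                  rb = 1.5, res = 0.5)
  tops <- detect_treetops(chm)
  # 2 m apart < 2.975 m window of the lower apex: only the taller remains
  expect_identical(nrow(tops), 1L)
  expect_equal(tops$H, max(chm$values))
})

test_that("plateau ties break to the lowest (row, col) index", {
  v <- matrix(0, 10, 10)
  v[4, 4] <- v[4, 6] <- 5               # two equal maxima 1 m apart
  chm <- raster_grid(v, 0, 0, 0.5)
  tops <- detect_treetops(chm)
  expect_identical(nrow(tops), 1L)
  expect_identical(c(tops$row, tops$col), c(4L, 4L))
})

test_that("detected heights respect the CHM bounds and the threshold", {
  sc <- plane_cones_scene(seed = 9, density = 120)
  lab <- classify_ground(sc$syn$cloud)
  ext <- c(min(lab$x), max(lab$x), min(lab$y), max(lab$y))
  dtm <- interpolate_dtm(lab, res = 0.5, extent = ext)
  chm <- build_chm(build_dsm(lab, grid = dtm), dtm)
  tops <- detect_treetops(chm)
  expect_true(all(tops$H >= 2.6))
  expect_true(all(tops$H <= max(chm$values)))
  expect_identical(nrow(tops), nrow(sc$trees))
})

test_that("crown segments partition canopy cells around their own apex", {
  chm <- cone_chm(apexes = rbind(c(5, 10), c(14, 10)), H = c(8, 9),
                  rb = 2, res = 0.5)
  tops <- detect_treetops(chm)
  segs <- segment_crowns(chm, tops)
  expect_identical(length(segs$segments), 2L)
  a <- segs$assignment$values
  # disjoint by construction; union within canopy cells
  expect_true(all(chm$values[a > 0] >= 2.6))
  for (s in segs$segments) {
    cells <- s$cells
    ids <- a[cbind(cells[, "row"], cells[, "col"])]
    expect_true(all(ids == s$tree_id))
    # each crown contains its own seed cell
    expect_true(any(cells[, "row"] == s$seed["row"] &
                      cells[, "col"] == s$seed["col"]))
  }
})

test_that("segmentation is invariant to the ordering of the treetops", {
  chm <- cone_chm(apexes = rbind(c(5, 5), c(12, 6), c(7, 14)),
                  H = c(8, 9, 7), rb = 2, res = 0.5)
  tops <- detect_treetops(chm)
  rev_tops <- tops[rev(seq_len(nrow(tops))), ]
  s1 <- segment_crowns(chm, tops)
  s2 <- segment_crowns(chm, rev_tops)
  expect_identical(s1$assignment$values, s2$assignment$values)
})

test_that("duplicate treetops are rejected", {
  chm <- cone_chm(apexes = rbind(c(5, 5)), H = 8, rb = 2, res = 0.5)
  tops <- detect_treetops(chm)
  expect_error(segment_crowns(chm, rbind(tops, tops)), "distinct")
})

test_that("crown area comes from the convex hull by the shoelace formula", {
  chm <- raster_grid(matrix(5, 10, 10), 0, 0, 0.5)
  seg <- list(segments = list(list(
    tree_id = 1L,
    cells = cbind(row = c(4L, 4L, 5L, 5L), col = c(4L, 5L, 4L, 5L)),
    seed = c(row = 4L, col = 4L), n_cells = 4L)), assignment = NULL)
  m <- crown_metrics(seg, chm)
  expect_equal(m$CA, 0.25)                 # 0.5 m square of cell centres
  expect_equal(m$H, 5)
})

test_that("degenerate one-cell crowns fall back to the cell area", {
  chm <- raster_grid(matrix(5, 10, 10), 0, 0, 0.5)
  seg <- list(segments = list(list(
    tree_id = 1L, cells = cbind(row = 4L, col = 4L),
    seed = c(row = 4L, col = 4L), n_cells = 1L)), assignment = NULL)
  expect_warning(m <- crown_metrics(seg, chm), "degenerate")
  expect_equal(m$CA, 0.25)
})

test_that("the hull of a dense conical crown approximates its base disc", {
  chm <- cone_chm(apexes = rbind(c(10, 10)), H = 8, rb = 2, res = 0.1,
                  xmax = 20, ymax = 20)
  tops <- detect_treetops(chm)
  segs <- segment_crowns(chm, tops, seed_frac = 0.01, crown_frac = 0.01,
                         min_height = 0.005)
  m <- crown_metrics(segs, chm)
  expect_equal(m$CA, pi * 2^2, tolerance = 0.15)
})

test_that("detections are matched to the nearest planted position", {
  trees <- data.frame(tree_id = 1:3, site = 1, block = 1, family = 1:3,
                      x = c(0, 10, 20), y = c(0, 0, 0))
  met <- data.frame(tree_id = 1:3, x = c(0.4, 10.2, 40), y = c(0.3, 0.1, 0),
                    H = c(8, 9, 10), CA = c(3, 4, 5))
  expect_message(out <- match_treetops(met, trees), "unmatched")
  expect_identical(nrow(out), 2L)
  expect_identical(out$planted_id, c(1L, 2L))
})
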