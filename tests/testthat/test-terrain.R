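test_that("points on one horizontal plane are all classified ground", {
  set.seed(1)
  pc <- point_cloud(runif(4000) * 20, runif(4000) * 20, rep(55, 4000))
  lab <- classify_ground(pc)
  expect_true(all(lab$label == "ground"))
})

test_that("a tall dense blob over a plane is classified non-ground", {
  set.seed(2)
  n <- 6000
  px <- runif(n) * 30; py <- runif(n) * 30
  blob <- runif(800, 14, 16)
  pc <- point_cloud(c(px, blob), c(py, runif(800, 14, 16)),
                    c(rep(20, n), rep(25, 800)))
  lab <- classify_ground(pc, threshold = 0.5)
  truth <- c(rep("ground", n), rep("non-ground", 800))
  expect_identical(lab$label, truth)
})

test_that("a single point settles the cloth and is ground", {
  lab <- classify_ground(point_cloud(1, 2, 3))
  expect_identical(lab$label, "ground")
  expect_error(classify_ground(point_cloud(numeric(), numeric(),
                                           numeric())), "empty")
})

test_that("ground classification is perfect on a noise-free plane+cones scene", {
  sc <- plane_cones_scene(seed = 3, density = 120)
  lab <- classify_ground(sc$syn$cloud)
  tp <- sum(lab$label == "ground" & sc$syn$true_label == "ground")
  fp <- sum(lab$label == "ground" & sc$syn$true_label == "non-ground")
  fn <- sum(lab$label == "non-ground" & sc$syn$true_label == "ground")
  expect_identical(fp, 0L)
  expect_identical(fn, 0L)
  expect_gt(tp, 0L)
})

test_that("KNN-IDW of constant elevations is exactly constant", {
  set.seed(4)
  pc <- point_cloud(runif(200) * 10, runif(200) * 10, rep(10, 200))
  dtm <- interpolate_dtm(pc, res = 0.5)
  expect_true(all(abs(dtm$values - 10) < 1e-12))
})

test_that("KNN-IDW recovers a dense sloping plane within 5 cm", {
  set.seed(5)
  n <- 20000
  px <- runif(n) * 20; py <- runif(n) * 20
  pc <- point_cloud(px, py, 0.1 * px)
  dtm <- interpolate_dtm(pc, res = 0.5, extent = c(0, 20, 0, 20))
  ctr <- canopygain:::cell_centers(dtm)
  truth <- outer(ctr$y, ctr$x, function(yy, xx) 0.1 * xx)
  expect_lt(max(abs(dtm$values - truth)), 0.05)
})

test_that("interpolated cells stay inside the neighbours' elevation range", {
  set.seed(6)
  pc <- point_cloud(runif(300) * 10, runif(300) * 10, rnorm(300, 50, 5))
  dtm <- interpolate_dtm(pc, res = 1, k = 10)
  expect_true(all(dtm$values >= min(pc$z) - 1e-12))
  expect_true(all(dtm$values <= max(pc$z) + 1e-12))
})

test_that("a cell centre coincident with a point takes its elevation exactly", {
  # cell centre of cell (1,1) at res 1 over [0,2]^2 is (0.5, 0.5)
  pc <- point_cloud(c(0.5, 1.7, 0.2, 1.1, 1.9), c(0.5, 0.3, 1.8, 1.2, 1.9),
                    c(42, 50, 55, 60, 65))
  dtm <- interpolate_dtm(pc, res = 1, k = 3, extent = c(0, 2, 0, 2))
  expect_identical(dtm$values[1, 1], 42)
})

test_that("too few ground points give an actionable error", {
  pc <- point_cloud(1:3, 1:3, 1:3)
  expect_error(interpolate_dtm(pc, k = 10), "smaller k")
})

test_that("the DSM keeps the highest point per cell and fills gaps", {
  pc <- point_cloud(c(0.2, 0.3, 5.2), c(0.2, 0.3, 5.3), c(3, 7, 12))
  dsm <- build_dsm(pc, res = 1, extent = c(0, 6, 0, 6))
  expect_identical(dsm$values[1, 1], 7)     # max of 3 and 7
  expect_identical(dsm$values[6, 6], 12)
  expect_true(all(is.finite(dsm$values)))   # empty cells filled
})

test_that("the CHM is the clamped DSM-DTM difference", {
  v <- matrix(runif(25, 90, 95), 5, 5)
  dtm <- raster_grid(v, 0, 0, 1)
  dsm0 <- raster_grid(v, 0, 0, 1)
  expect_true(all(build_chm(dsm0, dtm)$values == 0))
  dsm8 <- raster_grid(v + 8, 0, 0, 1)
  expect_true(all(build_chm(dsm8, dtm)$values == 8))
  # negative differences clamp to zero
  dsmn <- raster_grid(v - 0.2, 0, 0, 1)
  expect_true(all(build_chm(dsmn, dtm)$values == 0))
  bad <- raster_grid(v, 0, 0, 0.5)
  expect_error(build_chm(dsm0, bad), "geometr")
})

test_that("the CHM is invariant to a constant elevation shift", {
  sc <- plane_cones_scene(seed = 7, density = 60, n_cones = 2)
  cl <- sc$syn$cloud
  ext <- c(min(cl$x), max(cl$x), min(cl$y), max(cl$y))
  chm_of <- function(cloud) {
    lab <- classify_ground(cloud)
    dtm <- interpolate_dtm(lab, res = 0.5, extent = ext)
    build_chm(build_dsm(lab, grid = dtm), dtm)
  }
  shifted <- point_cloud(cl$x, cl$y, cl$z + 100)
  expect_equal(chm_of(cl)$values, chm_of(shifted)$values, tolerance = 1e-9)
})

test_that("CHM apex heights track the planted tree heights", {
  sc <- plane_cones_scene(seed = 8, density = 150)
  lab <- classify_ground(sc$syn$cloud)
  ext <- c(min(lab$x), max(lab$x), min(lab$y), max(lab$y))
  dtm <- interpolate_dtm(lab, res = 0.5, extent = ext)
  chm <- build_chm(build_dsm(lab, grid = dtm), dtm)
  for (i in seq_len(nrow(sc$trees))) {
    ci <- canopygain:::cell_index(chm, sc$trees$x[i], sc$trees$y[i])
    expect_equal(chm$values[ci$row, ci$col], sc$trees$true_height[i],
                 tolerance = 2 * chm$res)
  }
})
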