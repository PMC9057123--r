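test_that("trial simulation honours the single-tree-plot layout", {
  d <- trial_design(n_sites = 1, n_blocks_per_site = 14, n_families = 20)
  tr <- simulate_trial(d, genetic_architecture(), seed = 42)
  expect_equal(nrow(tr), 280)
  expect_true(all(table(tr$family) == 14))
  # one tree per family per block
  expect_true(all(table(tr$block, tr$family) == 1))
  # planted on the spacing grid: coordinates are multiples of half-spacings
  expect_true(all(abs(tr$x / 1 - round(tr$x / 1)) < 1e-9))
})

test_that("with all variances off every tree gets the grand mean exactly", {
  z <- c(height = 0, dbh = 0, crown_diameter = 0)
  arch <- genetic_architecture(mean = c(height = 8, dbh = 12,
                                        crown_diameter = 3),
                               var_family = z, var_block = z,
                               var_residual = z)
  tr <- simulate_trial(trial_design(1, 3, 5), arch, seed = 1)
  expect_identical(unique(tr$true_height), 8)
  expect_identical(unique(tr$true_dbh), 12)
  expect_identical(unique(tr$true_crown_diameter), 3)
})

test_that("simulation is deterministic under a fixed seed", {
  d <- trial_design(2, 4, 10)
  a <- genetic_architecture()
  expect_identical(simulate_trial(d, a, seed = 7),
                   simulate_trial(d, a, seed = 7))
  expect_false(identical(simulate_trial(d, a, seed = 7),
                         simulate_trial(d, a, seed = 8)))
})

test_that("a non-PSD family correlation matrix is rejected by name", {
  cm <- canopygain:::default_family_cor()
  cm[1, 2] <- cm[2, 1] <- 0.99
  cm[1, 3] <- cm[3, 1] <- 0.99
  cm[2, 3] <- cm[3, 2] <- -0.99
  expect_error(genetic_architecture(cor_family = cm), "cor_family")
})

test_that("empirical family-effect variance matches the architecture", {
  z <- c(height = 0, dbh = 0, crown_diameter = 0)
  arch <- genetic_architecture(
    mean = c(height = 8, dbh = 12, crown_diameter = 3),
    var_family = c(height = 0.6, dbh = 1, crown_diameter = 0.04),
    var_block = z, var_residual = z)
  tr <- simulate_trial(trial_design(1, 1, 400), arch, seed = 3)
  # with block and residual variance off, trait = mean + family effect
  expect_equal(var(tr$true_height), 0.6, tolerance = 0.15)
})

test_that("survival thinning removes roughly the requested fraction", {
  d <- trial_design(2, 14, 20)
  tr <- simulate_trial(d, genetic_architecture(), seed = 5, survival = 0.9)
  expect_lt(nrow(tr), 560)
  expect_gt(nrow(tr), 560 * 0.8)
})

test_that("a treeless scene renders points exactly on the terrain", {
  ter <- terrain_function()
  empty <- simulate_trial(trial_design(1, 1, 2),
                          genetic_architecture(), seed = 1)[0, ]
  syn <- render_point_cloud(empty, terrain = ter, density = 50,
                            noise_sd = 0, seed = 2, extent = c(0, 10, 0, 5))
  expect_true(all(syn$true_label == "ground"))
  expect_lt(max(abs(syn$cloud$z - ter(syn$cloud$x, syn$cloud$y))), 1e-9)
})

test_that("the rendered apex height equals true height when noise is off", {
  ter <- terrain_function(slope = c(0, 0), amplitude = 0, z0 = 10)
  tr <- data.frame(tree_id = 1L, site = 1, block = 1, family = 1,
                   x = 5, y = 5, true_height = 7.5, true_dbh = 10,
                   true_crown_diameter = 3)
  class(tr) <- c("true_trees", "data.frame")
  syn <- render_point_cloud(tr, terrain = ter, density = 80, noise_sd = 0,
                            seed = 4)
  apex <- max(syn$cloud$z) - ter(5, 5)
  expect_equal(apex, 7.5, tolerance = 1e-12)
})

test_that("point counts follow the requested density", {
  empty <- simulate_trial(trial_design(1, 1, 2),
                          genetic_architecture(), seed = 1)[0, ]
  syn <- render_point_cloud(empty, density = 100, noise_sd = 0, seed = 9,
                            extent = c(0, 10, 0, 5))
  # area 50 m^2 at 100 pts/m^2: within Poisson error of 5000
  expect_lt(abs(nrow(syn$cloud) - 5000), 4 * sqrt(5000))
})

test_that("rendering rejects a non-positive density", {
  tr <- simulate_trial(trial_design(1, 1, 2), genetic_architecture(),
                       seed = 1)
  expect_error(render_point_cloud(tr, density = -5), "density")
})

test_that("rendering is deterministic and labels match the geometry", {
  tr <- simulate_trial(trial_design(1, 2, 3), genetic_architecture(),
                       seed = 6)
  a <- render_point_cloud(tr, density = 40, noise_sd = 0.02, seed = 11)
  b <- render_point_cloud(tr, density = 40, noise_sd = 0.02, seed = 11)
  expect_identical(a$cloud, b$cloud)
  expect_identical(a$true_label, b$true_label)
  expect_equal(sum(is.na(a$tree_id)), sum(a$true_label == "ground"))
})
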