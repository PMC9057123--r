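# Synthetic progeny trials with known genetic architecture, rendered as raw
# point clouds. The generator emulates an open-pollinated half-sib trial:
# complete randomized blocks with one tree per family per block (the
# single-tree-plot layout; incomplete alpha-lattice blocking is deliberately
# simplified away since the downstream mixed model only uses block and family
# labels).

# run expr with a fixed RNG state, restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Specify the layout of a progeny trial
#'
#' Single-tree-plot randomized blocks: every block holds one tree of every
#' family on a regular planting grid.
#'
#' @param n_sites number of sites.
#' @param n_blocks_per_site blocks per site.
#' @param n_families number of open-pollinated families (default 20).
#' @param spacing_x,spacing_y planting spacing in metres (defaults 2 and 3).
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(n_sites = 2, n_blocks_per_site = 14, n_families = 20,
                         spacing_x = 2, spacing_y = 3) {
  stopifnot(n_sites >= 1, n_blocks_per_site >= 1, n_families >= 1,
            spacing_x > 0, spacing_y > 0)
  structure(list(n_sites = as.integer(n_sites),
                 n_blocks_per_site = as.integer(n_blocks_per_site),
                 n_families = as.integer(n_families),
                 trees_per_block = as.integer(n_families),
                 spacing_x = spacing_x, spacing_y = spacing_y),
            class = "trial_design")
}

default_family_cor <- function() {
  m <- matrix(c(1.0, 0.8, 0.6,
                0.8, 1.0, 0.5,
                0.6, 0.5, 1.0), 3, 3)
  dimnames(m) <- list(c("height", "dbh", "crown_diameter"),
                      c("height", "dbh", "crown_diameter"))
  m
}

#' Specify the genetic architecture of the simulated traits
#'
#' Three traits are simulated per tree: total height (m), diameter at breast
#' height (cm) and crown diameter (m). Each trait decomposes as grand mean +
#' family effect + block effect + residual; family effects are drawn once per
#' family from a multivariate normal with correlation `cor_family`, so the
#' simulation truth for the genetic correlation between two traits is the
#' corresponding entry of `cor_family`.
#'
#' Default variances give narrow-sense heritability 0.25 under the
#' 2.5-coefficient half-sib estimator for every trait, inside the range
#' typically reported for young pine growth traits.
#'
#' @param mean,var_family,var_block,var_residual named numeric vectors over
#'   the traits `height`, `dbh`, `crown_diameter` (units m, cm, m and their
#'   squares).
#' @param cor_family 3x3 family-effect correlation matrix (unit diagonal,
#'   positive semidefinite).
#' @return an object of class `genetic_architecture`.
#' @export
genetic_architecture <- function(
    mean = c(height = 8, dbh = 12, crown_diameter = 3),
    var_family = c(height = 0.4, dbh = 1.6, crown_diameter = 0.04),
    var_block = c(height = 0.4, dbh = 1.6, crown_diameter = 0.04),
    var_residual = c(height = 3.2, dbh = 12.8, crown_diameter = 0.32),
    cor_family = default_family_cor()) {
  traits <- c("height", "dbh", "crown_diameter")
  for (v in list(mean, var_family, var_block, var_residual))
    stopifnot(all(traits %in% names(v)))
  if (any(var_family < 0) || any(var_block < 0) || any(var_residual < 0))
    stop("variance components must be >= 0")
  cor_family <- as.matrix(cor_family)
  if (!isTRUE(all.equal(cor_family, t(cor_family))) ||
      any(abs(diag(cor_family) - 1) > 1e-8) ||
      min(eigen(cor_family, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8)
    stop("cor_family is not a symmetric positive semidefinite ",
         "correlation matrix with unit diagonal")
  structure(list(traits = traits, mean = mean[traits],
                 var_family = var_family[traits], var_block = var_block[traits],
                 var_residual = var_residual[traits],
                 cor_family = cor_family[traits, traits]),
            class = "genetic_architecture")
}

# matrix square root via eigendecomposition; tolerates PSD (zero eigenvalues)
psd_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate a breeding trial with known trait values
#'
#' Draws family, block and residual effects under `arch`, randomizes families
#' onto the planting grid within each block, and returns one row per planted
#' tree. Family effects are shared across blocks and sites (no
#' genotype-by-environment interaction). Crown diameters and heights are
#' floored at small positive values so every tree is renderable.
#'
#' @param design a [trial_design()].
#' @param arch a [genetic_architecture()].
#' @param seed integer seed; the same seed reproduces the trial exactly.
#' @param survival probability that a planted tree is alive (default 1);
#'   thinning is applied after layout so positions stay on the grid.
#' @return a data frame of class `true_trees` with columns
#'   `tree_id, site, block, family, x, y, true_height, true_dbh,
#'   true_crown_diameter`. `block` labels are unique across sites.
#' @export
simulate_trial <- function(design, arch, seed, survival = 1) {
  stopifnot(inherits(design, "trial_design"),
            inherits(arch, "genetic_architecture"),
            survival > 0, survival <= 1)
  with_seed(seed, {
    nt <- length(arch$traits)
    nf <- design$n_families
    # family effects: one draw per family, correlated across traits
    Sf <- diag(sqrt(arch$var_family)) %*% arch$cor_family %*%
      diag(sqrt(arch$var_family))
    fam_eff <- matrix(rnorm(nf * nt), nf, nt) %*% psd_sqrt(Sf)
    colnames(fam_eff) <- arch$traits

    # block footprint: trees in a near-square grid inside each block
    tpb <- design$trees_per_block
    bx <- ceiling(sqrt(tpb)); by <- ceiling(tpb / bx)
    block_w <- bx * design$spacing_x
    block_h <- by * design$spacing_y
    nb <- design$n_blocks_per_site
    tiles_x <- ceiling(sqrt(nb)); tiles_y <- ceiling(nb / tiles_x)
    site_gap <- 20

    rows <- vector("list", design$n_sites * nb)
    gblock <- 0L
    for (s in seq_len(design$n_sites)) {
      site_x0 <- (s - 1) * (tiles_x * block_w + site_gap)
      for (b in seq_len(nb)) {
        gblock <- gblock + 1L
        tx0 <- site_x0 + ((b - 1) %% tiles_x) * block_w
        ty0 <- ((b - 1) %/% tiles_x) * block_h
        fam <- sample.int(nf)                 # families onto positions
        pos <- seq_len(tpb) - 1L
        px <- tx0 + (pos %% bx + 0.5) * design$spacing_x
        py <- ty0 + (pos %/% bx + 0.5) * design$spacing_y
        blk_eff <- rnorm(nt, 0, sqrt(arch$var_block))
        res <- matrix(rnorm(tpb * nt), tpb, nt) %*%
          diag(sqrt(arch$var_residual), nt)
        vals <- matrix(arch$mean, tpb, nt, byrow = TRUE) +
          fam_eff[fam, , drop = FALSE] +
          matrix(blk_eff, tpb, nt, byrow = TRUE) + res
        rows[[gblock]] <- data.frame(
          site = s, block = gblock, family = fam, x = px, y = py,
          true_height = pmax(vals[, 1], 0.5),
          true_dbh = pmax(vals[, 2], 0.5),
          true_crown_diameter = pmax(vals[, 3], 0.3))
      }
    }
    trees <- do.call(rbind, rows)
    trees <- cbind(tree_id = seq_len(nrow(trees)), trees)
    if (survival < 1)
      trees <- trees[runif(nrow(trees)) <= survival, , drop = FALSE]
    rownames(trees) <- NULL
    class(trees) <- c("true_trees", "data.frame")
    trees
  })
}

#' Write the simulated-tree table to CSV
#'
#' Columns: `tree_id,site,block,family,x,y,height_m,dbh_cm,crown_d_m`.
#'
#' @param trees output of [simulate_trial()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_true_trees <- function(trees, path) {
  d <- data.frame(tree_id = trees$tree_id, site = trees$site,
                  block = trees$block, family = trees$family,
                  x = trees$x, y = trees$y,
                  height_m = trees$true_height, dbh_cm = trees$true_dbh,
                  crown_d_m = trees$true_crown_diameter)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_true_trees
#' @export
read_true_trees <- function(path) {
  d <- utils::read.csv(path)
  out <- data.frame(tree_id = d$tree_id, site = d$site, block = d$block,
                    family = d$family, x = d$x, y = d$y,
                    true_height = d$height_m, true_dbh = d$dbh_cm,
                    true_crown_diameter = d$crown_d_m)
  class(out) <- c("true_trees", "data.frame")
  out
}

#' Analytic terrain surface
#'
#' A gentle plane plus a low-frequency sinusoid:
#' `z = z0 + sx*x + sy*y + amplitude * sin(2*pi*x/wavelength) *
#' cos(2*pi*y/wavelength)`. Returned as a vectorised function of (x, y) so
#' DTM error can be measured without a second interpolation.
#'
#' @param slope length-2 gradient (m/m) in x and y.
#' @param amplitude sinusoid amplitude (m).
#' @param wavelength sinusoid wavelength (m).
#' @param z0 base elevation (m).
#' @return a function `f(x, y)` returning elevations in metres.
#' @export
terrain_function <- function(slope = c(0.05, 0.02), amplitude = 0.3,
                             wavelength = 25, z0 = 100) {
  force(slope); force(amplitude); force(wavelength); force(z0)
  function(x, y)
    z0 + slope[1] * x + slope[2] * y +
      amplitude * sin(2 * pi * x / wavelength) * cos(2 * pi * y / wavelength)
}

#' Point densities of the three emulated survey flights (points per m^2)
#' @export
density_presets <- c(low = 100, mid = 250, high = 435)

#' Render simulated trees as an unlabelled 3D point cloud
#'
#' Ground points are sampled uniformly over the extent on the analytic
#' terrain; each living tree contributes points on a solid of revolution
#' (cone by default) whose apex sits `true_height` above the local ground and
#' whose base diameter equals `true_crown_diameter`, plus one deterministic
#' apex point so the defining vertex is always sampled. Crowns start at
#' `crown_base_frac * true_height` above ground, as conifer crowns are lifted
#' off the ground. Points carry no labels: classification is the terrain
#' module's job. Per-point truth is returned for oracle tests.
#'
#' @param trees a `true_trees` table (may have zero rows if `extent` given).
#' @param terrain a terrain function from [terrain_function()].
#' @param density point density, points per m^2 (> 0); see [density_presets].
#' @param noise_sd vertical Gaussian noise standard deviation (m).
#' @param seed integer seed.
#' @param shape crown solid: `"cone"` (default) or `"paraboloid"`.
#' @param crown_base_frac height fraction where the live crown starts.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; default is the tree
#'   bounding box padded by `buffer`.
#' @param buffer extent padding around the trees (m).
#' @return a list of class `synthetic_cloud` with elements `cloud`
#'   (unlabelled [point_cloud()]), `ground_elevation` (the terrain function),
#'   `true_label` (character, per point), and `tree_id` (integer per point,
#'   `NA` for ground points).
#' @export
render_point_cloud <- function(trees, terrain = terrain_function(),
                               density = density_presets[["low"]],
                               noise_sd = 0, seed = 1,
                               shape = c("cone", "paraboloid"),
                               crown_base_frac = 0.3,
                               extent = NULL, buffer = 3) {
  shape <- match.arg(shape)
  if (density <= 0) stop("point density must be > 0")
  if (is.null(extent)) {
    if (nrow(trees) == 0L)
      stop("need an explicit extent to render a treeless scene")
    extent <- c(min(trees$x) - buffer, max(trees$x) + buffer,
                min(trees$y) - buffer, max(trees$y) + buffer)
  }
  with_seed(seed, {
    area <- (extent[2] - extent[1]) * (extent[4] - extent[3])
    ng <- rpois(1, density * area)
    gx <- runif(ng, extent[1], extent[2])
    gy <- runif(ng, extent[3], extent[4])
    gz <- terrain(gx, gy) + if (noise_sd > 0) rnorm(ng, 0, noise_sd) else 0
    xs <- list(gx); ys <- list(gy); zs <- list(gz)
    ids <- list(rep(NA_integer_, ng))
    for (i in seq_len(nrow(trees))) {
      H <- trees$true_height[i]
      rmax <- trees$true_crown_diameter[i] / 2
      z0 <- terrain(trees$x[i], trees$y[i])
      nc <- rpois(1, density * pi * rmax^2)
      rho <- sqrt(runif(nc)) * rmax
      ang <- runif(nc, 0, 2 * pi)
      frac <- if (shape == "cone") rho / rmax else (rho / rmax)^2
      h <- H * (1 - (1 - crown_base_frac) * frac)
      cx <- c(trees$x[i], trees$x[i] + rho * cos(ang))
      cy <- c(trees$y[i], trees$y[i] + rho * sin(ang))
      cz <- z0 + c(H, h)
      if (noise_sd > 0) cz <- cz + rnorm(nc + 1, 0, noise_sd)
      xs[[i + 1L]] <- cx; ys[[i + 1L]] <- cy; zs[[i + 1L]] <- cz
      ids[[i + 1L]] <- rep(trees$tree_id[i], nc + 1L)
    }
    id <- unlist(ids)
    structure(list(
      cloud = point_cloud(unlist(xs), unlist(ys), unlist(zs)),
      ground_elevation = terrain,
      true_label = ifelse(is.na(id), "ground", "non-ground"),
      tree_id = id), class = "synthetic_cloud")
  })
}

#' @export
print.synthetic_cloud <- function(x, ...) {
  cat(sprintf("synthetic_cloud: %d points (%d ground, %d crown)\n",
              nrow(x$cloud), sum(x$true_label == "ground"),
              sum(x$true_label == "non-ground")))
  invisible(x)
}
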