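# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written against the model definitions, not
# against the package internals, so the two routes stay independent.

# Direct REML log-likelihood through the dense covariance matrix
#   V = ve I + vb Zb Zb' + vf Zf Zf',
#   l = -1/2 [ log|V| + log|X'V^-1 X| + (y - X bhat)' V^-1 (y - X bhat) ].
# Used as the brute-force likelihood oracle on tiny instances.
reml_loglik_direct <- function(y, X, Zb, Zf, vb, vf, ve) {
  n <- length(y)
  V <- ve * diag(n) + vb * tcrossprod(Zb) + vf * tcrossprod(Zf)
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(-Inf)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  beta <- solve(XtViX, XtVi %*% y)
  r <- y - X %*% beta
  ld_v <- determinant(V, logarithm = TRUE)$modulus
  ld_x <- determinant(XtViX, logarithm = TRUE)$modulus
  -0.5 * as.numeric(ld_v + ld_x + t(r) %*% Vi %*% r)
}

# Iteratively refined grid search over (vb, vf, ve): zooms a 9^3 grid around
# the incumbent until the spacing is < 1e-6 per component.
grid_reml_oracle <- function(y, X, Zb, Zf,
                             init = c(1, 1, 1), span = 4, rounds = 24) {
  best <- log(init)
  width <- rep(log(span), 3)
  best_val <- -Inf
  for (r in seq_len(rounds)) {
    gb <- seq(best[1] - width[1], best[1] + width[1], length.out = 9)
    gf <- seq(best[2] - width[2], best[2] + width[2], length.out = 9)
    ge <- seq(best[3] - width[3], best[3] + width[3], length.out = 9)
    for (a in gb) for (b in gf) for (cc in ge) {
      v <- reml_loglik_direct(y, X, Zb, Zf, exp(a), exp(b), exp(cc))
      if (v > best_val) { best_val <- v; best <- c(a, b, cc) }
    }
    width <- width * 0.45
    if (max(width) < 1e-7) break
  }
  list(varcomp = c(block = exp(best[1]), family = exp(best[2]),
                   residual = exp(best[3])), loglik = best_val)
}

# Expected-mean-squares ANOVA estimator for a balanced randomized complete
# block design with both factors random (the classical closed form that REML
# reproduces under balance).
anova_varcomp <- function(y, block, family) {
  f <- nlevels(factor(family)); b <- nlevels(factor(block))
  ms <- anova(lm(y ~ factor(block) + factor(family)))
  mse <- ms["Residuals", "Mean Sq"]
  c(family = (ms["factor(family)", "Mean Sq"] - mse) / b,
    block = (ms["factor(block)", "Mean Sq"] - mse) / f,
    residual = mse)
}

# Trait-level simulation of the paper-sized trial through the synth module,
# returning the table the genetics module consumes
sim_trial_traits <- function(seed, n_sites = 2, n_blocks = 14,
                             n_families = 20,
                             vf = 1, vb = 1, ve = 8, rg = 0.8) {
  cm <- canopygain:::default_family_cor()
  cm[1, 2] <- cm[2, 1] <- rg
  arch <- genetic_architecture(
    mean = c(height = 8, dbh = 12, crown_diameter = 3),
    var_family = c(height = vf, dbh = vf, crown_diameter = 0.04),
    var_block = c(height = vb, dbh = vb, crown_diameter = 0.04),
    var_residual = c(height = ve, dbh = ve, crown_diameter = 0.32),
    cor_family = cm)
  simulate_trial(trial_design(n_sites, n_blocks, n_families), arch,
                 seed = seed)
}

# A flat or gently sloped plane with isolated conifer cones, rendered
# noise-free: the canonical terrain/detection oracle scene
plane_cones_scene <- function(seed = 1, density = 120, n_cones = 6,
                              slope = c(0.05, 0.02), height = 8,
                              crown_d = 3, spacing = 8) {
  ter <- terrain_function(slope = slope, amplitude = 0, z0 = 50)
  xs <- (seq_len(n_cones) - 0.5) * spacing
  trees <- data.frame(tree_id = seq_len(n_cones), site = 1, block = 1,
                      family = seq_len(n_cones),
                      x = xs, y = rep(c(5, 11), length.out = n_cones),
                      true_height = height + seq_len(n_cones) * 0.3,
                      true_dbh = 12, true_crown_diameter = crown_d)
  class(trees) <- c("true_trees", "data.frame")
  syn <- render_point_cloud(trees, terrain = ter, density = density,
                            noise_sd = 0, seed = seed,
                            extent = c(0, n_cones * spacing, 0, 16))
  list(trees = trees, syn = syn, terrain = ter)
}

# analytic conical CHM on a raster: crowns of base radius rb, apex height H
cone_chm <- function(apexes, H, rb, res = 0.5, xmax = 20, ymax = 20) {
  g <- raster_grid(matrix(0, ymax / res, xmax / res), 0, 0, res)
  ctr <- canopygain:::cell_centers(g)
  for (i in seq_len(nrow(apexes))) {
    d <- sqrt(outer(ctr$y - apexes[i, 2], ctr$x - apexes[i, 1],
                    function(dy, dx) dy^2 + dx^2))
    g$values <- pmax(g$values, H[i] * pmax(1 - d / rb, 0))
  }
  g
}
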