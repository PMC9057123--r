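test_that("heritability follows the 2.5-coefficient family fraction", {
  expect_identical(heritability(0, 1, 1), 0)
  expect_equal(heritability(1, 1, 1), 2.5 / 3)
  set.seed(20)
  for (i in 1:20) {
    v <- runif(3, 0.01, 10)
    frac <- v[1] / sum(v)
    expect_equal(heritability(v[1], v[2], v[3]) / frac, 2.5)
  }
  expect_error(heritability(0, 0, 0), "phenotypic variance")
})

test_that("genetic correlation is the normalised family covariance", {
  expect_identical(genetic_correlation(sqrt(6 * 7), 6, 7), 1)
  expect_identical(genetic_correlation(0, 2, 3), 0)
  expect_equal(genetic_correlation(2, 4, 4), 0.5)
  expect_error(genetic_correlation(1, 0, 4), "> 0")
})

test_that("genetic gain matches enumeration on a known breeding-value set", {
  bv <- c(a = 4, b = 2, c = 0, d = -2, e = -4)
  expect_identical(genetic_gain(bv, 1), 0)
  expect_identical(genetic_gain(bv, 0.2), 4)
  expect_identical(genetic_gain(bv, 0.4), 3)
  expect_error(genetic_gain(numeric(), 0.5), "empty")
  # percent variant
  expect_equal(genetic_gain(bv, 0.2, percent = TRUE, trait_mean = 8),
               100 * 4 / 8)
})

test_that("genetic gain is non-negative and non-increasing in the ratio", {
  set.seed(21)
  bv <- rnorm(20)
  ratios <- seq(0.05, 1, by = 0.05)
  gains <- vapply(ratios, function(r) genetic_gain(bv, r), 0)
  expect_true(all(gains >= 0))
  expect_true(all(diff(gains) <= 1e-12))
})

test_that("REML equals the balanced-design ANOVA estimator to 1e-6", {
  tr <- sim_trial_traits(seed = 101, n_sites = 1, n_blocks = 14)
  fit <- fit_family_reml(tr$true_height, block = tr$block,
                         family = tr$family)
  an <- anova_varcomp(tr$true_height, tr$block, tr$family)
  expect_true(all(an > 0))                 # interior solution on this draw
  expect_equal(unname(fit$varcomp["family"]), unname(an["family"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["block"]), unname(an["block"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["residual"]), unname(an["residual"]),
               tolerance = 1e-6)
})

test_that("REML matches a grid-search likelihood oracle on a 3x3 trial", {
  tr <- sim_trial_traits(seed = 202, n_sites = 1, n_blocks = 3,
                         n_families = 3, vf = 2, vb = 1, ve = 1)
  y <- tr$true_height
  blk <- factor(tr$block); fam <- factor(tr$family)
  fit <- fit_family_reml(y, block = blk, family = fam)
  X <- matrix(1, length(y), 1)
  Zb <- stats::model.matrix(~ blk - 1); Zf <- stats::model.matrix(~ fam - 1)
  orc <- grid_reml_oracle(y, X, Zb, Zf,
                          init = pmax(fit$varcomp[c("block", "family",
                                                    "residual")], 0.05))
  expect_equal(unname(fit$varcomp["family"]), unname(orc$varcomp["family"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$varcomp["block"]), unname(orc$varcomp["block"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$varcomp["residual"]),
               unname(orc$varcomp["residual"]), tolerance = 1e-4)
})

test_that("zero family signal is estimated at the boundary", {
  tr <- sim_trial_traits(seed = 303, n_sites = 1, n_blocks = 20,
                         n_families = 10, vf = 0, vb = 1, ve = 8)
  fit <- fit_family_reml(tr$true_height, block = tr$block,
                         family = tr$family)
  expect_lt(fit$varcomp["family"], 0.05 * fit$varcomp["residual"])
})

test_that("duplicating every observation leaves variance ratios stable", {
  tr <- sim_trial_traits(seed = 404, n_sites = 1, n_blocks = 14)
  y <- tr$true_height
  f1 <- fit_family_reml(y, block = tr$block, family = tr$family)
  f2 <- fit_family_reml(c(y, y), block = c(tr$block, tr$block),
                        family = c(tr$family, tr$family))
  r1 <- f1$varcomp["family"] / f1$varcomp["residual"]
  r2 <- f2$varcomp["family"] / f2$varcomp["residual"]
  expect_equal(unname(r2), unname(r1), tolerance = 0.15)
})

test_that("family BLUPs centre near zero and drive the gain table", {
  tr <- sim_trial_traits(seed = 505, n_sites = 1, n_blocks = 14)
  fit <- fit_family_reml(tr$true_height, block = tr$block,
                         family = tr$family)
  expect_lt(abs(mean(breeding_values(fit))), 0.05)
  expect_equal(breeding_values(fit, double = TRUE),
               2 * breeding_values(fit))
})

test_that("a trait paired with itself has genetic correlation one", {
  tr <- sim_trial_traits(seed = 606, n_sites = 1, n_blocks = 14)
  fit <- fit_family_reml2(tr$true_height, tr$true_height,
                          block = tr$block, family = tr$family)
  expect_equal(fit$r_g, 1, tolerance = 1e-8)
})

test_that("independent family effects give a correlation centred on zero", {
  rg <- vapply(1:8, function(i) {
    tr <- sim_trial_traits(seed = 700 + i, rg = 0)
    fit_family_reml2(tr$true_height, tr$true_dbh, site = tr$site,
                     block = tr$block, family = tr$family)$r_g
  }, 0)
  expect_lt(abs(mean(rg)), 0.25)
  expect_true(all(rg >= -1 & rg <= 1))
})

test_that("the bivariate fit recovers a known family correlation", {
  rg <- vapply(1:10, function(i) {
    tr <- sim_trial_traits(seed = 800 + i, rg = 0.8)
    fit_family_reml2(tr$true_height, tr$true_dbh, site = tr$site,
                     block = tr$block, family = tr$family)$r_g
  }, 0)
  expect_equal(mean(rg), 0.8, tolerance = 0.15)
  expect_true(all(rg >= -1 & rg <= 1))
})

test_that("the genetic summary has a coherent shape", {
  tr <- sim_trial_traits(seed = 909)
  d <- data.frame(site = tr$site, block = tr$block, family = tr$family,
                  height = tr$true_height, dbh = tr$true_dbh)
  gs <- summarize_genetics(d, traits = c("height", "dbh"))
  # pooled + one row per site per trait
  expect_identical(nrow(gs$h2), 2L * 3L)
  expect_true(all(gs$h2$h2 >= 0 & gs$h2$h2 <= 2.5))
  expect_identical(gs$r_g, t(gs$r_g))
  expect_true(all(diag(gs$r_g) == 1))
  expect_true(all(abs(gs$r_g) <= 1))
  # gains: per trait, per site level, per ratio
  expect_identical(nrow(gs$gains), 2L * 3L * 3L)
  expect_true(all(gs$gains$gain >= 0))
  # single trait, single site: exactly one heritability
  d1 <- d[d$site == 1, ]
  gs1 <- summarize_genetics(d1, traits = "height")
  expect_identical(nrow(gs1$h2), 1L)
})

test_that("pooled heritability lies between the per-site estimates", {
  # site 2 has inflated residual variance: its h2 is lower, and the pooled
  # fit (site fixed) must land in between
  tr <- sim_trial_traits(seed = 111, n_sites = 2, n_blocks = 14)
  y <- tr$true_height
  infl <- tr$site == 2
  mu <- mean(y[infl])
  y[infl] <- mu + (y[infl] - mu) * 2     # doubles all site-2 components' SD
  set.seed(1)
  y <- y + rnorm(length(y), 0, ifelse(infl, 3, 0))  # extra site-2 residual
  d <- data.frame(site = tr$site, block = tr$block, family = tr$family,
                  height = y)
  gs <- summarize_genetics(d, traits = "height")
  h <- setNames(gs$h2$h2, gs$h2$site)
  expect_true(h["pooled"] >= min(h["1"], h["2"]) - 0.02)
  expect_true(h["pooled"] <= max(h["1"], h["2"]) + 0.02)
})
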