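---
title: "From drone point clouds to genetic gain: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From drone point clouds to genetic gain: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(canopygain)
```

`canopygain` estimates breeding-relevant genetic parameters for a conifer
progeny trial from a photogrammetric point cloud. This vignette explains the
models, the defaults and why they were chosen, what the synthetic-trial
generator does and does not emulate, and the numerical decisions that a
maintainer would otherwise have to reverse-engineer.

## 1. The trial and its genetic model

The target design is an open-pollinated half-sib progeny trial planted as
single-tree plots: each block holds exactly one tree of each family, blocks
are replicated within (possibly several) sites, trees stand on a regular
spacing grid (2 m x 3 m by default). For a trait $y$ the model is

$$ y = Xm + Z_1 b + Z_2 f + e, $$

with intercept and site as fixed effects $m$, and block effects
$b \sim N(0, \sigma_b^2 I)$, family effects $f \sim N(0, \sigma_f^2 I)$ and
residuals $e \sim N(0, \sigma_e^2 I)$ random. Narrow-sense heritability uses
a relationship coefficient of $1/2.5$ rather than the textbook $1/4$ for
half-sibs,

$$ h^2 = \frac{2.5\,\sigma_f^2}{\sigma_f^2 + \sigma_b^2 + \sigma_e^2}, $$

because open-pollinated pine families are typically more related than ideal
half-sibs; the coefficient is an argument (`coefficient = 2.5`) for users
who prefer 4. The genetic correlation between traits $i$ and $j$ is
$r_g = \sigma_{fij} / \sqrt{\sigma_{fi}^2 \sigma_{fj}^2}$ from a bivariate
fit with unstructured 2x2 family and residual covariance matrices and
per-trait block variances. Breeding values are the family BLUPs (the
conventional half-sib parental doubling is available via
`breeding_values(fit, double = TRUE)` but off by default: ranking and
UAV-versus-ground comparisons are invariant to it). Genetic gain at
selection ratio $p$ is the mean BLUP of the top $\lceil p\,n_f \rceil$
families minus the mean over all families, reported in trait units
(a percent-of-mean variant exists via `percent = TRUE`).

Assumptions worth stating: family effects are shared across sites (no
genotype-by-environment interaction term), blocks are complete (the
incomplete alpha-lattice blocking of real trials is simplified to
randomized complete blocks — the model only consumes block and family
labels), and per-site heritabilities are obtained by refitting within each
site, since a single pooled model with site as a fixed effect cannot give
site-specific variance components.

## 2. REML: formulation and numerics

The REML log-likelihood is evaluated in Henderson mixed-model-equation form,

$$ -2\ell_R = \log|R| + \log|G| + \log|C| + y'Py + \text{const}, $$

where $C$ is the $(p+q)\times(p+q)$ MME coefficient matrix. This needs only
a Cholesky factorization of $C$ (about 50 x 50 for the univariate
paper-sized trial, 100 x 100 bivariate), never an $n \times n$ solve, so a
fit takes tens of milliseconds and large recovery simulations stay cheap.

Numerical choices:

* **Parameterization.** Log standard deviations (univariate); log-diagonal
  and free off-diagonal Cholesky entries of the 2x2 family and residual
  covariances (bivariate). The Cholesky form guarantees positive
  semidefiniteness, hence $r_g \in [-1, 1]$ by construction.
* **Optimization.** Quasi-Newton (L-BFGS-B) from three fixed starting
  points, a Nelder-Mead polish, then bound-projected Newton steps with
  numerical derivatives until the interior gradient is below $10^{-9}$.
  The Newton polish is what lets REML match the closed-form balanced-design
  ANOVA estimator to $10^{-6}$ (a property the test suite checks).
* **Boundaries.** Traits are standardized internally; log-SDs are bounded in
  $[-10, 6]$. A component pinned at the lower bound is reported as exactly 0
  with a `boundary` flag. The bivariate residual log-diagonals are floored
  at $-4$ (a conditional residual SD of ~2% of the trait SD): below that the
  likelihood of collinear traits is an unbounded ridge, and a measurement
  floor of that size is physically reasonable for photogrammetric traits.
* **Degenerate pairs.** If two traits are (nearly) collinear
  (|phenotypic correlation| > 0.99 — e.g. belowground biomass, which is a
  deterministic monotone transform of predicted DBH), the joint model is not
  identifiable. `fit_family_reml2()` then returns the documented
  approximation: univariate fits per trait with the family correlation
  estimated as the correlation of the univariate family BLUPs (exactly 1
  for a trait with itself, no SE). `summarize_genetics()` uses the same
  approximation, with a warning, if a joint fit fails to converge on a
  small sample.
* **Standard errors.** $SE(r_g)$ by the delta method at the REML optimum,
  using the numerical observed information; `NA` when the information matrix
  is not invertible (e.g. at a boundary).
* **Non-convergence** raises a classed condition
  (`fam_reml_nonconvergence`) carrying the best point found.

## 3. Point cloud to per-tree traits

**Ground filter.** A simplified cloth simulation: invert z, drop a 0.5 m
cloth grid under gravity onto the per-cell highest inverted point, smooth
with `rigidness = 2` neighbour-averaging passes per step, classify points
within 0.5 m of the settled cloth as ground. The cloth stopping surface in
cells containing no points is pre-filled by inverse-distance interpolation
so the cloth cannot sag through unsampled gaps. The cloth parameters
(resolution 0.5 m, rigidness 2, threshold 0.5 m) are the common defaults of
the published filter; the source methodology names the filter but not its
settings.

**Rasters.** Lower-left origin, half-open cells, cell-centre sampling —
stated explicitly because conventions differ between GIS stacks. DTM:
KNN-IDW with k = 10, power 2 (the convention of the R lidar toolchain);
a cell centre coinciding with a ground point takes its elevation exactly.
DSM: highest point per cell, empty cells filled by KNN-IDW from non-empty
cells. CHM = DSM − DTM clamped at 0 (noise below the interpolated terrain is
not vegetation). Rasters are written as plain ESRI ASCII grids.

**Detection.** A CHM cell is a treetop iff its height is at least 2.6 m and
strictly greater than every cell centre within radius
$0.05 H + 2.6$ m, evaluated at its own height. The 2.6 m threshold is the
Methods-section value (the source abstract says "three meters"; the Methods
value is implemented). The formula is used as a *radius*, following the
symbol definition in the source, although the surrounding text says
"diameter" — with the radius reading, apexes closer together than ~2.6 m
suppress each other, so guaranteed-complete detection requires apex spacing
above the window radius. That is exactly what the "easy" synthetic preset
provides (7 m x 7 m spacing), and detection completeness is asserted only
there. Exact plateau ties break to the lowest (row, col) index; this is
documented because noise-free synthetic cones do produce ties.

**Crowns.** Seeded 4-neighbour region growing: a cell joins if it exceeds
45% of the seed height and 55% of the running region mean (the cited
segmentation algorithm's conventional defaults), lies within half the 5 m
maximum crown diameter of the seed (the "hard radius" reading of the
maximum-diameter rule), and is above the minimum height. Cells reachable by
two crowns in the same round go to the nearer seed; growth is invariant to
the input order of the treetops (they are re-sorted canonically). Crown
area is the shoelace area of the convex hull of member cell centres; crowns
with fewer than three non-collinear cells fall back to
`n_cells * resolution^2` with a warning.

**DBH and biomass.** DBH is invisible from above, so it is predicted by the
additive smooth model $DBH = a + f_1(H) + f_2(CA) + \varepsilon$ — cubic
regression splines, 10 knots per covariate, smoothing parameters by REML via
the penalized-spline/mixed-model equivalence (delegated to `mgcv::gam`,
which implements exactly this estimator). The basis shrinks automatically
(with a warning) when the training set cannot support it; fewer than 10
training records is an error; a zero-variance response short-circuits to the
constant model (REML smoothing selection is undefined there). Predictions
clamp covariates to the training ranges with a warning — a penalized spline
has no business extrapolating. Biomass follows the species' power-law
allometry ($M_a = 0.0861 D^{2.072} H^{0.452} + 0.002$,
$M_b = 0.0269 D^{2.394} H^{0} + 0.058$; D cm, H m, biomass kg). Ground-truth
biomass is obtained by applying the same allometry to field-measured DBH and
height — that is how the reference workflow produces its "ground truth" (no
destructive sampling), and the package mirrors it. Uncertainty in predicted
DBH is *not* propagated into biomass; this matches the reference workflow
and is a known limitation.

## 4. The synthetic-trial generator

`simulate_trial()` draws family effects once per family from a multivariate
normal over the three traits (height m, DBH cm, crown diameter m) with a
specified correlation matrix, block effects and residuals independently per
trait, and randomizes families onto the planting grid within each block.
`render_point_cloud()` samples ground points as a Poisson-count uniform
scatter on an analytic terrain (plane + low-frequency sinusoid, returned to
the caller so DTM error is measurable without a second interpolation) and
crown points on a solid of revolution — a cone by default, conifer-like,
with a paraboloid option — whose apex sits exactly `true_height` above the
local ground. One deterministic apex point per tree guarantees the defining
vertex is sampled, so the rendered apex height equals the true height
exactly at `noise_sd = 0`. Crowns start at 30% of tree height
(`crown_base_frac`), as conifer live crowns are lifted off the ground; this
also keeps crown points well above the 0.5 m ground-filter threshold.
Density presets 100 / 250 / 435 points per m² mirror the three survey
flights of the reference workflow.

Default architecture: trait means 8 m / 12 cm / 3 m; variance components
scaled so each trait has $h^2 = 0.25$ under the 2.5-coefficient estimator
(e.g. height 0.4 / 0.4 / 3.2), inside the range reported for young pine
growth traits; family correlations 0.8 (height-DBH), 0.6 and 0.5. The
`paperlike` preset is the full two-site, 20-family, 14-blocks-per-site trial
(560 planted positions) with 8% mortality; `easy` is a one-site, 20-family,
4-block stand at 7 m spacing with noise-free rendering (the
detection-completeness oracle); `tiny` is a 9-tree (3 families x 3 blocks)
smoke fixture.

What the generator does **not** emulate: photogrammetric reconstruction
artifacts (occlusion, matching noise, vegetation penetration), RGB/radiance,
crown asymmetry, lean, or within-crown gaps. Passing tests therefore
demonstrate the correctness of the algorithms under their stated geometric
assumptions, not the field accuracy of photogrammetry itself — with real
clouds the ground filter and DBH model will inherit whatever noise the
reconstruction adds.

## 5. Verification strategy and problem sizes

The test suite pairs every stage with an independent oracle:

* terrain: noise-free plane+cones scenes at 120 points/m², ~6 crowns over
  ~770 m²; ground precision and recall must be exactly 1 and DTM RMSE
  < 0.05 m against the analytic terrain;
* detection: the 80-tree `easy` stand at 100 points/m²; detected count must
  equal planted count, per-tree height error < 0.25 m;
* REML: balanced-design equivalence with the ANOVA expected-mean-squares
  estimator to 1e-6 (20 families x 14 blocks), and equivalence with an
  iteratively refined grid search over the dense-matrix REML likelihood to
  1e-4 on a 3-family x 3-block instance;
* recovery: 200 simulated two-site trials with variance components
  (1, 1, 8) — true $h^2 = 0.25$ — and family correlation 0.8; the mean
  estimate must land within 0.05 of the true heritability and within 0.1 of
  the true correlation (trait-level simulation, no rendering, so the whole
  suite stays under ten minutes on one core);
* pipeline: byte-identical output bundles for identical configuration and
  seed.

These sizes were chosen as the smallest instances that exercise each
property without Monte-Carlo ambiguity.

## 6. Known limitations

* Detection completeness degrades at the real trial's 2 m x 3 m spacing
  under the radius reading of the variable window (see §3); the package
  reproduces the workflow faithfully but dense stands will under-detect
  shorter neighbours of tall trees.
* Crown area from region growing underestimates the geometric crown base
  area by design (the growing thresholds trim the lowest crown fringe);
  crown-area comparisons should therefore be relative, not absolute.
* No G×E interaction term, no pedigree beyond half-sib families, no spatial
  autocorrelation correction.
* DBH-prediction uncertainty is not propagated into biomass or the genetic
  analysis.
* The bivariate fallback for near-collinear traits reports no $SE(r_g)$.
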