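# Quantitative genetics of the trial: REML variance components under the
# half-sib family model
#
#   y = X m + Z1 b + Z2 f + e,   b ~ N(0, sigma_b^2 I),
#                                f ~ N(0, sigma_f^2 I),  e ~ N(0, sigma_e^2 I)
#
# with intercept and site as fixed effects. The REML log-likelihood is
# evaluated in Henderson mixed-model-equation form,
#   -2 l_R = log|R| + log|G| + log|C| + y'Py + const,
# which only needs the Cholesky factor of the (p + q) x (p + q) coefficient
# matrix C, never an n x n solve. Variances are optimized on the log-SD
# scale (quasi-Newton from three fixed starts, then Newton polish with
# numerical derivatives); the bivariate model parameterizes the 2x2 family
# and residual covariances by their Cholesky factors so they stay positive
# semidefinite and the genetic correlation stays in [-1, 1] by construction.

# numerical gradient / Hessian (central differences)
num_grad <- function(fn, p, h = 1e-5) {
  vapply(seq_along(p), function(i) {
    e <- rep(0, length(p)); e[i] <- h
    (fn(p + e) - fn(p - e)) / (2 * h)
  }, 0)
}

num_hess <- function(fn, p, h = 1e-4) {
  k <- length(p)
  H <- matrix(0, k, k)
  f0 <- fn(p)
  for (i in seq_len(k)) {
    ei <- rep(0, k); ei[i] <- h
    H[i, i] <- (fn(p + ei) - 2 * f0 + fn(p - ei)) / h^2
    for (j in seq_len(i - 1)) {
      ej <- rep(0, k); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (fn(p + ei + ej) - fn(p + ei - ej) -
           fn(p - ei + ej) + fn(p - ei - ej)) / (4 * h^2)
    }
  }
  H
}

# minimize fn from several starts: L-BFGS-B, Nelder-Mead polish, then
# bound-projected Newton steps (numerical derivatives) for high-precision
# convergence, including optima pinned at a variance boundary
optimize_reml <- function(fn, starts, lower = -10, upper = 6) {
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(o)) o <- optim(s, fn, method = "Nelder-Mead",
                               control = list(maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  o <- optim(best$par, fn, method = "Nelder-Mead",
             control = list(reltol = 1e-12, maxit = 3000))
  if (o$value < best$value) best <- o
  p <- pmin(pmax(best$par, lower), upper)
  for (it in 1:10) {
    g <- num_grad(fn, p)
    pinned <- (p <= lower + 1e-5 & g > 0) | (p >= upper - 1e-5 & g < 0)
    free <- which(!pinned)
    if (!length(free) || max(abs(g[free])) < 1e-9) break
    H <- num_hess(fn, p)
    s <- tryCatch(solve(H[free, free, drop = FALSE], g[free]),
                  error = function(e) NULL)
    if (is.null(s) || any(!is.finite(s))) break
    step <- rep(0, length(p)); step[free] <- s
    ok <- FALSE
    for (halv in 0:10) {                     # backtracking line search
      pn <- pmin(pmax(p - step / 2^halv, lower), upper)
      if (fn(pn) <= fn(p)) { p <- pn; ok <- TRUE; break }
    }
    if (!ok) break
  }
  # converged when the gradient vanishes on interior coordinates and points
  # outward on bound-pinned ones (a variance shrunk to the boundary)
  g <- num_grad(fn, p)
  at_lo <- p <= lower + 1e-5; at_hi <- p >= upper - 1e-5
  interior_ok <- all(abs(g[!at_lo & !at_hi]) < 1e-2)
  bound_ok <- all(g[at_lo] > -1e-2) && all(g[at_hi] < 1e-2)
  list(par = p, value = fn(p), converged = interior_ok && bound_ok)
}

# Approximate bivariate summary from two univariate fits: family correlation
# estimated as the correlation of the univariate family BLUPs. Used for
# (near-)collinear trait pairs, where the joint REML surface is a singular
# ridge, and as the documented fallback when joint REML does not converge.
reml2_blup_approx <- function(y1, y2, site, block, family, ct = NULL) {
  if (is.null(ct)) ct <- suppressWarnings(stats::cor(y1, y2))
  f1 <- fit_family_reml(y1, site = site, block = block, family = family)
  f2 <- fit_family_reml(y2, site = site, block = block, family = family)
  rg <- suppressWarnings(stats::cor(f1$blup_family, f2$blup_family))
  if (!is.finite(rg)) rg <- sign(ct)
  v1 <- f1$varcomp["family"]; v2 <- f2$varcomp["family"]
  cf <- rg * sqrt(v1 * v2)
  Sf <- matrix(c(v1, cf, cf, v2), 2, 2)
  r1 <- f1$varcomp["residual"]; r2 <- f2$varcomp["residual"]
  ce <- ct * sqrt(r1 * r2)
  Se <- matrix(c(r1, ce, ce, r2), 2, 2)
  dimnames(Sf) <- dimnames(Se) <- list(c("t1", "t2"), c("t1", "t2"))
  structure(list(
    cov_family = Sf, cov_residual = Se,
    var_block = c(f1$varcomp["block"], f2$varcomp["block"]),
    r_g = rg, r_g_se = NA_real_,
    blup_family = cbind(t1 = f1$blup_family, t2 = f2$blup_family),
    fixed = f1$fixed, loglik = NA_real_, converged = TRUE,
    degenerate = TRUE, n = f1$n,
    n_family = f1$n_family, n_block = f1$n_block), class = "fam_reml2")
}

nonconvergence_error <- function(msg, best) {
  stop(structure(class = c("fam_reml_nonconvergence", "error", "condition"),
                 list(message = msg, call = sys.call(-1), best = best)))
}

#' Fit the univariate half-sib family mixed model by REML
#'
#' Estimates block, family and residual variance components for one trait
#' under `y = Xm + Z1 b + Z2 f + e` with intercept (and site, when given) as
#' fixed effects, and returns BLUPs of the family and block effects from the
#' mixed-model equations at the REML optimum.
#'
#' @param y numeric trait vector.
#' @param site optional site labels (fixed effect); `NULL` for a single site.
#' @param block block labels (unique across sites; random).
#' @param family family labels (random).
#' @return an object of class `fam_reml` with components `varcomp` (named
#'   vector: `family`, `block`, `residual`), `fixed`, `blup_family`,
#'   `blup_block`, `loglik` (REML), `converged`, and `boundary` (logical per
#'   component: estimate pinned at zero).
#' @export
fit_family_reml <- function(y, site = NULL, block, family) {
  keep <- is.finite(y)
  y <- y[keep]
  block <- factor(block[keep]); family <- factor(family[keep])
  if (!is.null(site)) site <- factor(site[keep])
  n <- length(y)
  if (nlevels(family) < 2 || nlevels(block) < 2 || n < 4)
    stop("need >= 2 families, >= 2 blocks and >= 4 observations")
  X <- if (is.null(site) || nlevels(site) < 2) matrix(1, n, 1,
         dimnames = list(NULL, "(Intercept)"))
       else stats::model.matrix(~site)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  Zb <- stats::model.matrix(~ block - 1)
  Zf <- stats::model.matrix(~ family - 1)
  W <- cbind(X, Zb, Zf)
  p <- ncol(X); B <- ncol(Zb); Fq <- ncol(Zf)
  WtW <- crossprod(W); Wty <- crossprod(W, y); yty <- sum(y^2)
  sy <- stats::sd(y)
  if (sy == 0) sy <- 1
  ys2 <- yty / sy^2; Wtys <- Wty / sy

  # negative REML log-likelihood (up to constant), par = log SDs on the
  # standardized scale: (block, family, residual)
  nll <- function(par) {
    v <- exp(2 * par)
    Ginv <- c(rep(0, p), rep(1 / v[1], B), rep(1 / v[2], Fq))
    C <- WtW / v[3] + diag(Ginv)
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    rhs <- Wtys / v[3]
    theta <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    yPy <- ys2 / v[3] - sum(theta * rhs)
    0.5 * (n * log(v[3]) + B * log(v[1]) + Fq * log(v[2]) +
             2 * sum(log(diag(R))) + yPy)
  }

  starts <- list(log(sqrt(c(1, 1, 1) / 3)),
                 log(sqrt(c(0.05, 0.05, 0.9))),
                 log(sqrt(c(0.45, 0.45, 0.1))))
  opt <- optimize_reml(nll, starts)
  if (!opt$converged)
    nonconvergence_error("REML did not converge", best = opt)

  v <- exp(2 * opt$par)
  boundary <- opt$par < -8
  v[boundary] <- 0
  vG <- pmax(v[1:2], 1e-12)                # for BLUP solve at the boundary
  Ginv <- c(rep(0, p), rep(1 / vG[1], B), rep(1 / vG[2], Fq))
  C <- WtW / v[3] + diag(Ginv)
  theta <- solve(C, Wtys / v[3]) * sy
  names(theta) <- colnames(W)

  structure(list(
    varcomp = c(family = v[2] * sy^2, block = v[1] * sy^2,
                residual = v[3] * sy^2),
    fixed = theta[seq_len(p)],
    blup_block = stats::setNames(theta[p + seq_len(B)], levels(block)),
    blup_family = stats::setNames(theta[p + B + seq_len(Fq)], levels(family)),
    loglik = -(opt$value + (n - p) / 2 * log(2 * pi) +
                 (n - p) * log(sy)),
    converged = opt$converged,
    boundary = c(family = boundary[2], block = boundary[1],
                 residual = boundary[3]),
    n = n, n_family = Fq, n_block = B), class = "fam_reml")
}

#' @export
print.fam_reml <- function(x, ...) {
  cat(sprintf("half-sib family REML fit: n = %d, %d families, %d blocks\n",
              x$n, x$n_family, x$n_block))
  vc <- x$varcomp
  cat(sprintf("  variance components: family %.4g, block %.4g, residual %.4g\n",
              vc["family"], vc["block"], vc["residual"]))
  cat(sprintf("  h2 (coef 2.5) = %.3f, REML loglik = %.3f%s\n",
              heritability(vc["family"], vc["block"], vc["residual"]),
              x$loglik,
              if (any(x$boundary)) " [boundary component(s) set to 0]" else ""))
  invisible(x)
}

#' @export
coef.fam_reml <- function(object, ...) object$fixed

#' @export
summary.fam_reml <- function(object, ...) {
  vc <- object$varcomp
  out <- list(varcomp = vc,
              h2 = heritability(vc["family"], vc["block"], vc["residual"]),
              breeding_values = sort(object$blup_family, decreasing = TRUE),
              loglik = object$loglik)
  class(out) <- "summary.fam_reml"
  out
}

#' @export
print.summary.fam_reml <- function(x, ...) {
  cat("variance components:\n"); print(x$varcomp)
  cat(sprintf("narrow-sense h2 (coef 2.5): %.3f\n", x$h2))
  cat("family breeding values (BLUPs), best first:\n")
  print(round(x$breeding_values, 4))
  invisible(x)
}

#' Family breeding values from a fitted model
#'
#' The breeding value of a family is its BLUP from the REML fit. For
#' open-pollinated half-sib families the parental breeding value is
#' conventionally twice the family mean deviation; that doubling is off by
#' default because selection ranks and UAV-vs-ground comparisons are
#' invariant to it.
#'
#' @param fit a [fit_family_reml()] object.
#' @param double if `TRUE`, multiply BLUPs by 2 (parental scale).
#' @return named numeric vector of per-family breeding values.
#' @export
breeding_values <- function(fit, double = FALSE) {
  stopifnot(inherits(fit, "fam_reml"))
  fit$blup_family * if (double) 2 else 1
}

#' Narrow-sense heritability from half-sib variance components
#'
#' `h2 = coefficient * var_family / (var_family + var_block + var_residual)`.
#' The default coefficient 2.5 (rather than the textbook 4 = 1/0.25 for
#' half-sibs) reflects a relationship coefficient of 1/2.5, appropriate when
#' open-pollinated families are more related than ideal half-sibs.
#'
#' @param var_family,var_block,var_residual variance components (>= 0).
#' @param coefficient relationship coefficient multiplier (default 2.5).
#' @return narrow-sense heritability (unitless, in `[0, coefficient]`).
#' @export
heritability <- function(var_family, var_block, var_residual,
                         coefficient = 2.5) {
  tot <- var_family + var_block + var_residual
  if (any(tot <= 0)) stop("total phenotypic variance must be > 0")
  unname(coefficient * var_family / tot)
}

#' Genetic correlation between two traits
#'
#' `r_g = cov_family / sqrt(var_family_i * var_family_j)`.
#'
#' @param cov_family family covariance between the traits.
#' @param var_family_i,var_family_j family variances of the two traits (> 0).
#' @return genetic correlation.
#' @export
genetic_correlation <- function(cov_family, var_family_i, var_family_j) {
  if (any(var_family_i <= 0) || any(var_family_j <= 0))
    stop("family variances must be > 0 to define a genetic correlation")
  unname(cov_family / sqrt(var_family_i * var_family_j))
}

#' Fit the bivariate half-sib family mixed model by REML
#'
#' Joint model for two traits observed on the same trees: unstructured 2x2
#' family and residual covariance matrices (parameterized by their Cholesky
#' factors, so positive semidefiniteness — and hence a genetic correlation in
#' `[-1, 1]` — is guaranteed), independent per-trait block variances, and
#' per-trait intercept and site fixed effects.
#'
#' @inheritParams fit_family_reml
#' @param y1,y2 the two trait vectors, same trees in the same order.
#' @return an object of class `fam_reml2` with `cov_family` and
#'   `cov_residual` (2x2 matrices), `var_block` (length 2), `r_g`, `r_g_se`
#'   (delta method), per-trait family BLUPs, `loglik` and `converged`.
#' @export
fit_family_reml2 <- function(y1, y2, site = NULL, block, family) {
  keep <- is.finite(y1) & is.finite(y2)
  y1 <- y1[keep]; y2 <- y2[keep]
  block <- factor(block[keep]); family <- factor(family[keep])
  if (!is.null(site)) site <- factor(site[keep])
  n <- length(y1)
  if (nlevels(family) < 2 || nlevels(block) < 2 || n < 4)
    stop("need >= 2 families, >= 2 blocks and >= 4 observations")
  X <- if (is.null(site) || nlevels(site) < 2) matrix(1, n, 1,
         dimnames = list(NULL, "(Intercept)"))
       else stats::model.matrix(~site)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  # (Near-)collinear traits make the bivariate model unidentifiable: the
  # residual covariance approaches singularity and the REML surface becomes
  # an unbounded ridge. One trait derived deterministically from the other
  # (e.g. belowground biomass from predicted DBH) is the common case. Fall
  # back to univariate fits of each trait and estimate the family correlation
  # as the correlation of the univariate family BLUPs (exactly 1 for a trait
  # with itself).
  ct <- suppressWarnings(stats::cor(y1, y2))
  if (is.finite(ct) && abs(ct) > 0.99)
    return(reml2_blup_approx(y1, y2, site, block, family, ct))
  Zb <- stats::model.matrix(~ block - 1)
  Zf <- stats::model.matrix(~ family - 1)
  W0 <- cbind(X, Zb, Zf)
  p <- ncol(X); B <- ncol(Zb); Fq <- ncol(Zf)
  K <- p + B + Fq
  s1 <- stats::sd(y1); s2 <- stats::sd(y2)
  if (s1 == 0) s1 <- 1
  if (s2 == 0) s2 <- 1
  z1 <- y1 / s1; z2 <- y2 / s2
  M0 <- crossprod(W0)
  u1 <- crossprod(W0, z1); u2 <- crossprod(W0, z2)
  g11 <- sum(z1^2); g12 <- sum(z1 * z2); g22 <- sum(z2^2)
  ib <- p + seq_len(B); ifam <- p + B + seq_len(Fq)

  # par = (lf1, cf, lf2, lb1, lb2, le1, ce, le2): log-diagonal and
  # off-diagonal Cholesky entries of Sigma_f and Sigma_e, log SDs of blocks
  unpack <- function(par) {
    Lf <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2, 2)
    Le <- matrix(c(exp(par[6]), par[7], 0, exp(par[8])), 2, 2)
    list(Sf = Lf %*% t(Lf), Se = Le %*% t(Le), vb = exp(2 * par[4:5]))
  }

  nll <- function(par) {
    cm <- unpack(par)
    Sei <- tryCatch(solve(cm$Se), error = function(e) NULL)
    Sfi <- tryCatch(solve(cm$Sf), error = function(e) NULL)
    if (is.null(Sei) || is.null(Sfi)) return(1e10)
    C <- Sei %x% M0
    idx1 <- c(rep(0, p), rep(1 / cm$vb[1], B), rep(Sfi[1, 1], Fq))
    idx2 <- c(rep(0, p), rep(1 / cm$vb[2], B), rep(Sfi[2, 2], Fq))
    diag(C) <- diag(C) + c(idx1, idx2)
    C[cbind(ifam, K + ifam)] <- C[cbind(ifam, K + ifam)] + Sfi[1, 2]
    C[cbind(K + ifam, ifam)] <- C[cbind(K + ifam, ifam)] + Sfi[1, 2]
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    rhs <- c(Sei[1, 1] * u1 + Sei[1, 2] * u2,
             Sei[2, 1] * u1 + Sei[2, 2] * u2)
    theta <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    yRy <- Sei[1, 1] * g11 + 2 * Sei[1, 2] * g12 + Sei[2, 2] * g22
    logdetSe <- 2 * (par[6] + par[8]); logdetSf <- 2 * (par[1] + par[3])
    0.5 * (n * logdetSe + Fq * logdetSf +
             B * 2 * (par[4] + par[5]) +
             2 * sum(log(diag(R))) + yRy - sum(theta * rhs))
  }

  l0 <- log(sqrt(1 / 3))
  starts <- list(c(l0, 0, l0, l0, l0, l0, 0, l0),
                 c(log(0.2), 0.1, log(0.2), log(0.2), log(0.2),
                   log(0.9), 0.2, log(0.9)),
                 c(log(0.7), -0.1, log(0.7), log(0.3), log(0.3),
                   log(0.4), 0, log(0.4)))
  # residual Cholesky diagonals are floored (log scale -4, i.e. a conditional
  # residual SD of ~2% of the trait SD): with duplicated or perfectly
  # collinear traits the REML surface is otherwise unbounded along a
  # singular residual covariance
  lower <- c(-10, -6, -10, -10, -10, -4, -6, -4)
  opt <- optimize_reml(nll, starts, lower = lower, upper = 6)
  if (!opt$converged)
    nonconvergence_error("bivariate REML did not converge", best = opt)
  cm <- unpack(opt$par)
  scl <- c(s1, s2)
  Sf <- cm$Sf * (scl %o% scl); Se <- cm$Se * (scl %o% scl)
  vb <- cm$vb * scl^2
  dimnames(Sf) <- dimnames(Se) <- list(c("t1", "t2"), c("t1", "t2"))

  # BLUPs at the optimum
  Sei <- solve(cm$Se); Sfi <- solve(cm$Sf)
  C <- Sei %x% M0
  diag(C) <- diag(C) +
    c(c(rep(0, p), rep(1 / cm$vb[1], B), rep(Sfi[1, 1], Fq)),
      c(rep(0, p), rep(1 / cm$vb[2], B), rep(Sfi[2, 2], Fq)))
  C[cbind(ifam, K + ifam)] <- C[cbind(ifam, K + ifam)] + Sfi[1, 2]
  C[cbind(K + ifam, ifam)] <- C[cbind(K + ifam, ifam)] + Sfi[1, 2]
  rhs <- c(Sei[1, 1] * u1 + Sei[1, 2] * u2, Sei[2, 1] * u1 + Sei[2, 2] * u2)
  theta <- solve(C, rhs)
  blup1 <- stats::setNames(theta[ifam] * s1, levels(family))
  blup2 <- stats::setNames(theta[K + ifam] * s2, levels(family))

  rg <- genetic_correlation(Sf[1, 2], max(Sf[1, 1], 1e-12),
                            max(Sf[2, 2], 1e-12))
  # delta-method SE from the observed information of the REML surface
  rg_fun <- function(par) {
    S <- unpack(par)$Sf
    S[1, 2] / sqrt(max(S[1, 1] * S[2, 2], 1e-300))
  }
  rg_se <- tryCatch({
    Hn <- num_hess(nll, opt$par)
    Vp <- solve(Hn)
    gr <- num_grad(rg_fun, opt$par)
    se <- suppressWarnings(sqrt(drop(t(gr) %*% Vp %*% gr)))
    if (is.finite(se)) se else NA_real_
  }, error = function(e) NA_real_)

  structure(list(
    cov_family = Sf, cov_residual = Se, var_block = vb,
    r_g = rg, r_g_se = rg_se,
    blup_family = cbind(t1 = blup1, t2 = blup2),
    fixed = stats::setNames(theta[seq_len(p)] * s1, colnames(X)),
    loglik = -(opt$value + (2 * n - 2 * p) / 2 * log(2 * pi) +
                 (n - p) * (log(s1) + log(s2))),
    converged = opt$converged, n = n, n_family = Fq, n_block = B),
    class = "fam_reml2")
}

#' @export
print.fam_reml2 <- function(x, ...) {
  cat(sprintf("bivariate half-sib REML fit: n = %d trees, %d families\n",
              x$n, x$n_family))
  cat(sprintf("  family covariance: var %.4g / %.4g, cov %.4g\n",
              x$cov_family[1, 1], x$cov_family[2, 2], x$cov_family[1, 2]))
  cat(sprintf("  genetic correlation r_g = %.3f (SE %.3f)\n",
              x$r_g, x$r_g_se))
  invisible(x)
}

#' Realized genetic gain under truncation selection
#'
#' Mean breeding value of the top `ceiling(ratio * n_families)` families
#' minus the mean breeding value of all families. Ties in breeding value are
#' broken by family label.
#'
#' @param bv named numeric vector of per-family breeding values.
#' @param ratio selected fraction, in (0, 1].
#' @param percent if `TRUE`, express the gain as a percentage of
#'   `trait_mean`.
#' @param trait_mean trait grand mean, required when `percent = TRUE`.
#' @return the genetic gain (trait units, or percent of the mean).
#' @export
genetic_gain <- function(bv, ratio, percent = FALSE, trait_mean = NULL) {
  if (!length(bv)) stop("empty breeding-value set")
  stopifnot(ratio > 0, ratio <= 1)
  lab <- if (is.null(names(bv))) as.character(seq_along(bv)) else names(bv)
  o <- order(-bv, lab)
  n_sel <- ceiling(ratio * length(bv))
  gain <- mean(bv[o][seq_len(n_sel)]) - mean(bv)
  if (percent) {
    if (is.null(trait_mean) || trait_mean == 0)
      stop("percent gain needs a nonzero trait_mean")
    gain <- 100 * gain / trait_mean
  }
  unname(gain)
}

#' Genetic summary of a multi-trait trial
#'
#' Fits the univariate family model per trait (pooled across sites with site
#' as a fixed effect, and within each site) and the bivariate model per trait
#' pair (pooled), and assembles heritabilities, the genetic-correlation
#' matrix with standard errors, family breeding values, and genetic gains at
#' the given selection ratios.
#'
#' @param data data frame with columns `site`, `block`, `family` and the
#'   trait columns named in `traits`. Block labels are treated as nested in
#'   site.
#' @param traits character vector of trait column names (>= 1).
#' @param ratios selection ratios for the gain table (default 0.1, 0.2, 0.3).
#' @param coefficient heritability relationship coefficient (default 2.5).
#' @return an object of class `genetic_summary`: `h2` (data frame trait x
#'   site, `"pooled"` included), `r_g` and `r_g_se` (trait x trait matrices),
#'   `breeding_values` (family x trait, pooled fit), `gains` (data frame:
#'   trait, site, ratio, gain), `fits` (the pooled `fam_reml` objects).
#' @export
summarize_genetics <- function(data, traits, ratios = c(0.1, 0.2, 0.3),
                               coefficient = 2.5) {
  stopifnot(all(c("site", "block", "family") %in% names(data)),
            all(traits %in% names(data)), length(traits) >= 1)
  data$.block <- interaction(data$site, data$block, drop = TRUE)
  sites <- sort(unique(data$site))
  multi_site <- length(sites) > 1

  h2_rows <- list(); gain_rows <- list(); fits <- list(); bv_list <- list()
  for (tr in traits) {
    fit <- fit_family_reml(data[[tr]],
                           site = if (multi_site) data$site else NULL,
                           block = data$.block, family = data$family)
    fits[[tr]] <- fit
    vc <- fit$varcomp
    h2_rows[[length(h2_rows) + 1]] <- data.frame(
      trait = tr, site = "pooled",
      h2 = heritability(vc["family"], vc["block"], vc["residual"],
                        coefficient))
    bv_list[[tr]] <- breeding_values(fit)
    for (r in ratios)
      gain_rows[[length(gain_rows) + 1]] <- data.frame(
        trait = tr, site = "pooled", ratio = r,
        gain = genetic_gain(breeding_values(fit), r))
    if (multi_site) for (s in sites) {
      ds <- data[data$site == s, ]
      fs <- fit_family_reml(ds[[tr]], site = NULL, block = ds$.block,
                            family = ds$family)
      vcs <- fs$varcomp
      h2_rows[[length(h2_rows) + 1]] <- data.frame(
        trait = tr, site = as.character(s),
        h2 = heritability(vcs["family"], vcs["block"], vcs["residual"],
                          coefficient))
      for (r in ratios)
        gain_rows[[length(gain_rows) + 1]] <- data.frame(
          trait = tr, site = as.character(s), ratio = r,
          gain = genetic_gain(breeding_values(fs), r))
    }
  }

  nt <- length(traits)
  rg <- matrix(NA_real_, nt, nt, dimnames = list(traits, traits))
  rg_se <- rg
  diag(rg) <- 1; diag(rg_se) <- 0
  if (nt > 1) for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    bf <- tryCatch(
      fit_family_reml2(data[[traits[i]]], data[[traits[j]]],
                       site = if (multi_site) data$site else NULL,
                       block = data$.block, family = data$family),
      fam_reml_nonconvergence = function(e) {
        warning(sprintf(paste("joint REML for %s/%s did not converge;",
                              "using the univariate BLUP approximation"),
                        traits[i], traits[j]), call. = FALSE)
        reml2_blup_approx(data[[traits[i]]], data[[traits[j]]],
                          site = if (multi_site) data$site else NULL,
                          block = data$.block, family = data$family)
      })
    rg[i, j] <- rg[j, i] <- bf$r_g
    rg_se[i, j] <- rg_se[j, i] <- bf$r_g_se
  }

  fams <- sort(unique(as.character(data$family)))
  bv <- sapply(bv_list, function(v) v[fams])
  rownames(bv) <- fams

  structure(list(
    h2 = do.call(rbind, h2_rows),
    r_g = rg, r_g_se = rg_se,
    breeding_values = bv,
    gains = do.call(rbind, gain_rows),
    ratios = ratios, coefficient = coefficient, fits = fits),
    class = "genetic_summary")
}

#' @export
print.genetic_summary <- function(x, ...) {
  cat("genetic summary\n\nnarrow-sense heritability:\n")
  print(x$h2, row.names = FALSE)
  if (ncol(x$r_g) > 1) {
    cat("\ngenetic correlations (SE in parentheses):\n")
    m <- matrix(sprintf("%.2f (%.2f)", x$r_g, x$r_g_se),
                nrow(x$r_g), dimnames = dimnames(x$r_g))
    diag(m) <- "1"
    m[upper.tri(m)] <- ""
    print(m, quote = FALSE)
  }
  cat("\ngenetic gain at selection ratios",
      paste(x$ratios, collapse = ", "), "(pooled):\n")
  print(x$gains[x$gains$site == "pooled", ], row.names = FALSE)
  invisible(x)
}

#' Write the heritability, correlation and gain tables to CSV
#'
#' Three files: `<prefix>_h2.csv`, `<prefix>_rg.csv` (lower triangle with
#' SEs), `<prefix>_gains.csv`.
#'
#' @param x a [summarize_genetics()] result.
#' @param prefix path prefix for the output files.
#' @return the three paths, invisibly.
#' @export
write_genetic_summary <- function(x, prefix) {
  p1 <- paste0(prefix, "_h2.csv")
  utils::write.csv(x$h2, p1, row.names = FALSE, quote = FALSE)
  tr <- rownames(x$r_g)
  rows <- list()
  if (length(tr) > 1)
    for (i in 2:length(tr)) for (j in seq_len(i - 1))
      rows[[length(rows) + 1]] <- data.frame(
        trait_i = tr[i], trait_j = tr[j],
        r_g = x$r_g[i, j], se = x$r_g_se[i, j])
  p2 <- paste0(prefix, "_rg.csv")
  utils::write.csv(do.call(rbind, rows), p2, row.names = FALSE, quote = FALSE)
  p3 <- paste0(prefix, "_gains.csv")
  utils::write.csv(x$gains, p3, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3))
}
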