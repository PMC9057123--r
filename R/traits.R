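# Stem and biomass traits. DBH is not visible from above, so it is predicted
# from crown-visible covariates with an additive smooth model
# DBH = a + f1(height) + f2(crown area) + e, penalized cubic regression
# splines with the smoothing parameters chosen by REML. Biomass follows the
# species' published power-law allometry on DBH and height.

#' Fit the smooth DBH prediction model
#'
#' Penalized additive model `DBH ~ a + f1(H) + f2(CA)` with cubic regression
#' spline bases (10 knots per covariate by default) and REML estimation of
#' the smoothing parameters, via the mixed-model representation of penalized
#' splines. Each smooth is centred (sums to zero over the training data), so
#' the intercept is the training mean response.
#'
#' @param records data frame with numeric columns `H` (height, m), `CA`
#'   (crown area, m^2) and `DBH` (measured diameter at breast height, cm);
#'   rows with missing values are dropped.
#' @param k basis dimension per smooth (default 10); reduced automatically
#'   (with a warning) when the data cannot support it.
#' @return an object of class `dbh_model`.
#' @export
fit_dbh_model <- function(records, k = 10) {
  stopifnot(all(c("H", "CA", "DBH") %in% names(records)))
  d <- records[stats::complete.cases(records[, c("H", "CA", "DBH")]),
               c("H", "CA", "DBH")]
  n <- nrow(d)
  if (n < 10) stop("need at least 10 complete records to fit the DBH model")
  k_use <- function(xname) {
    nu <- length(unique(d[[xname]]))
    kk <- min(k, nu, floor(n / 2))
    if (kk < k)
      warning(sprintf("basis for %s reduced from %d to %d (n = %d, %d unique)",
                      xname, k, kk, n, nu))
    max(kk, 3L)
  }
  # a response with no variance breaks REML smoothing-parameter selection;
  # the correct fit is the constant model
  if (stats::sd(d$DBH) < 1e-10) {
    return(structure(list(
      gam = NULL, constant = d$DBH[1], k = c(H = 0L, CA = 0L),
      train_range = list(H = range(d$H), CA = range(d$CA)), train = d,
      diagnostics = c(r2 = NA_real_, rmse = 0, edf = 1, n = n),
      sigma2 = 0), class = "dbh_model"))
  }
  kh <- k_use("H"); kc <- k_use("CA")
  fit <- mgcv::gam(DBH ~ s(H, bs = "cr", k = kh) + s(CA, bs = "cr", k = kc),
                   data = d, method = "REML")
  pred <- as.numeric(predict(fit))
  acc <- suppressWarnings(validate_predictions(pred, d$DBH))
  structure(list(
    gam = fit,
    constant = NULL,
    k = c(H = kh, CA = kc),
    train_range = list(H = range(d$H), CA = range(d$CA)),
    train = d,
    diagnostics = c(r2 = acc$r2, rmse = acc$rmse,
                    edf = sum(fit$edf), n = n),
    sigma2 = fit$sig2), class = "dbh_model")
}

#' @export
print.dbh_model <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("constant DBH model: %.3f cm (zero-variance response)\n",
                x$constant))
    return(invisible(x))
  }
  d <- x$diagnostics
  cat(sprintf(paste0("smooth DBH model: DBH ~ a + f1(H) + f2(CA), cr splines",
                     " (k = %d/%d), REML\n"), x$k["H"], x$k["CA"]))
  cat(sprintf("  n = %d, training R^2 = %.3f, RMSE = %.3f cm, edf = %.2f\n",
              as.integer(d["n"]), d["r2"], d["rmse"], d["edf"]))
  cat(sprintf("  valid over H in [%.2f, %.2f] m, CA in [%.2f, %.2f] m^2\n",
              x$train_range$H[1], x$train_range$H[2],
              x$train_range$CA[1], x$train_range$CA[2]))
  invisible(x)
}

#' @export
coef.dbh_model <- function(object, ...) {
  if (!is.null(object$constant))
    return(c("(Intercept)" = object$constant))
  stats::coef(object$gam)
}

#' Predict DBH from height and crown area
#'
#' Covariates outside the training range are clamped to it (extrapolating a
#' penalized spline is meaningless), with a warning reporting how many points
#' were clamped.
#'
#' @param object a fitted [fit_dbh_model()] object.
#' @param H heights (m).
#' @param CA crown areas (m^2).
#' @param ... unused.
#' @return predicted DBH in cm.
#' @export
predict.dbh_model <- function(object, H, CA, ...) {
  stopifnot(length(H) == length(CA))
  rh <- object$train_range$H; rc <- object$train_range$CA
  n_clamp <- sum(H < rh[1] | H > rh[2] | CA < rc[1] | CA > rc[2])
  if (n_clamp > 0)
    warning(sprintf("%d point(s) outside the training range were clamped",
                    n_clamp))
  if (!is.null(object$constant)) return(rep(object$constant, length(H)))
  nd <- data.frame(H = pmin(pmax(H, rh[1]), rh[2]),
                   CA = pmin(pmax(CA, rc[1]), rc[2]))
  as.numeric(predict(object$gam, newdata = nd))
}

#' @rdname predict.dbh_model
#' @param model a fitted [fit_dbh_model()] object.
#' @export
predict_dbh <- function(model, H, CA) {
  if (!inherits(model, "dbh_model")) stop("model is not a fitted dbh_model")
  predict(model, H = H, CA = CA)
}

#' Serialize / restore a DBH model as versioned JSON
#'
#' The JSON file stores the schema version, basis dimensions, training data
#' and fitted coefficients. `load_dbh_model()` refits the (deterministic)
#' model from the stored training data and verifies the refitted coefficients
#' against the stored ones, so the file stays human-readable and portable
#' across R versions.
#'
#' @param model a `dbh_model`.
#' @param path JSON file path.
#' @return `save_dbh_model()` returns `path` invisibly; `load_dbh_model()`
#'   returns a `dbh_model`.
#' @export
save_dbh_model <- function(model, path) {
  jsonlite::write_json(list(
    format = "canopygain-dbh-model", version = 1L,
    k = as.list(model$k), train = model$train,
    coefficients = as.numeric(coef(model))), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dbh_model
#' @export
load_dbh_model <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(s$format, "canopygain-dbh-model"))
    stop("not a canopygain DBH model file: ", path)
  if (s$version != 1L) stop("unsupported DBH model version: ", s$version)
  model <- fit_dbh_model(s$train, k = max(s$k$H, s$k$CA, 3))
  if (max(abs(as.numeric(coef(model)) - s$coefficients)) > 1e-6)
    warning("refitted coefficients differ from the stored ones")
  model
}

#' Aboveground biomass from DBH and height
#'
#' Power-law allometry for slash pine:
#' `M_a = 0.0861 * D^2.072 * H^0.452 + 0.002` (kg), with D in cm and H in m.
#'
#' @param D diameter at breast height (cm), >= 0; vectorised.
#' @param H total height (m), > 0; vectorised.
#' @return aboveground biomass (kg).
#' @export
agb <- function(D, H) {
  if (any(D < 0)) stop("DBH must be >= 0")
  if (any(H <= 0)) stop("height must be > 0")
  0.0861 * D^2.072 * H^0.452 + 0.002
}

#' Belowground biomass from DBH
#'
#' `M_b = 0.0269 * D^2.394 * H^0 + 0.058` (kg): the height exponent of the
#' source allometry is zero, so height drops out and belowground biomass
#' depends on DBH alone.
#'
#' @param D diameter at breast height (cm), >= 0; vectorised.
#' @param H total height (m); accepted for interface symmetry with [agb()]
#'   and ignored (H^0 = 1).
#' @return belowground biomass (kg).
#' @export
bgb <- function(D, H = NULL) {
  if (any(D < 0)) stop("DBH must be >= 0")
  0.0269 * D^2.394 + 0.058
}

#' Prediction accuracy: R-squared and RMSE
#'
#' `R^2 = 1 - SS_res / SS_tot` about the observed mean;
#' `RMSE = sqrt(mean((predicted - observed)^2))`.
#'
#' @param predicted,observed equal-length numeric vectors, n >= 2.
#' @return a list with elements `r2`, `rmse`, `n`. When the observed values
#'   have zero variance `r2` is `NA` (undefined) with a warning.
#' @export
validate_predictions <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2)
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else {
    warning("observed values have zero variance; R^2 is undefined")
    NA_real_
  }
  list(r2 = r2, rmse = sqrt(mean((predicted - observed)^2)),
       n = length(observed))
}
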