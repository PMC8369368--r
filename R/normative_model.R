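#' Fit a per-region normative regression
#'
#' Ordinary least squares of a region's volume on the numeric design
#' columns, on the identity or log10 scale. The fitted object stores
#' everything single-case scoring needs: the coefficient vector, the
#' residual standard error `s_Vx` (denominator `n - k - 1`), the training
#' means and SDs of every predictor column, and the inverse of the
#' predictor correlation matrix `R^-1`.
#'
#' A rank-deficient design is an error (silent column dropping would
#' desynchronize `R^-1` from the coefficient vector); the error message
#' names the dependent columns. A perfect fit (`s_Vx` ~ 0) is flagged as
#' degenerate and scoring against it is disabled.
#'
#' @param design A [build_design_matrix()] result (training rows).
#' @param y Observed volumes on the raw scale (cm3), one per design row.
#' @param region Region id (bookkeeping only).
#' @param transform `"identity"` or `"log10"`. Log-scale outcomes must be
#'   strictly positive.
#' @return Object of class `normative_model`.
#' @export
fit_normative_model <- function(design, y, region = "region",
                                transform = c("identity", "log10")) {
  stopifnot(inherits(design, "design_matrix"))
  transform <- match.arg(transform)
  x <- design$x
  n <- nrow(x); k <- ncol(x)
  if (length(y) != n) abort_data("y length does not match design rows")
  if (n <= k + 1) abort_data("need n > k + 1 rows to fit (n = ", n,
                             ", k = ", k, ")")
  if (transform == "log10") {
    if (any(y <= 0))
      abort_data(region, ": log10 transform requires strictly positive volumes")
    y <- log10(y)
  }

  xa <- cbind(`(intercept)` = 1, x)
  qx <- qr(xa)
  if (qx$rank < ncol(xa)) {
    dep <- colnames(xa)[qx$pivot[(qx$rank + 1):ncol(xa)]]
    abort_data(region, ": design is rank-deficient; dependent column(s): ",
               paste(dep, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  fitted <- as.numeric(xa %*% coefs)
  res <- y - fitted
  rss <- sum(res^2)
  sigma <- sqrt(rss / (n - k - 1))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - rss / sst else NA_real_

  means <- colMeans(x)
  sds <- col_sds(x)
  R <- stats::cor(x)
  Rinv <- solve(R)

  structure(list(
    region = region, transform = transform,
    alpha = unname(coefs[1]), beta = coefs[-1],
    n = n, k = k, sigma = sigma, r2 = r2,
    sd_y = stats::sd(y),
    means = means, sds = sds, Rinv = Rinv,
    icv_center = design$icv_center,
    variant = design$spec$variant,
    train_range = list(
      age = if ("age" %in% colnames(x)) range(x[, "age"]) else c(-Inf, Inf),
      icv = if ("icv" %in% colnames(x)) range(x[, "icv"]) else c(-Inf, Inf)),
    degenerate = sigma < 1e-10
  ), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model> ", x$region, " (", x$variant, " variant, ",
      x$transform, " scale): n = ", x$n, ", k = ", x$k,
      ", s_Vx = ", format(x$sigma, digits = 4),
      ", R2 = ", format(x$r2, digits = 3),
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Fit norm models for many regions at once
#'
#' Builds one design matrix from the subjects and fits every requested
#' region, using the registry's log-scale flag to pick each region's
#' transform.
#'
#' @param subjects Training subject table (typically CN only).
#' @param volumes Row-aligned volume table.
#' @param regions Region ids (default: every registry region present in
#'   `volumes`).
#' @param variant Model variant, `"final"` or `"base"`.
#' @return Named list of `normative_model` objects.
#' @export
fit_region_models <- function(subjects, volumes,
                              regions = NULL, variant = "final") {
  reg_tab <- norm_regions()
  regions <- regions %||% intersect(reg_tab$region, names(volumes))
  dm <- build_design_matrix(subjects, formula_spec(variant))
  models <- lapply(regions, function(reg) {
    lg <- reg_tab$log_scale[match(reg, reg_tab$region)]
    if (is.na(lg)) lg <- FALSE
    fit_normative_model(dm, volumes[[reg]], region = reg,
                        transform = if (lg) "log10" else "identity")
  })
  stats::setNames(models, regions)
}

#' K-fold cross-validation of a norm regression
#'
#' Random partition into `k_folds` folds (seeded); each fold is predicted
#' from a fit on the remaining folds. Reports out-of-sample RMSE and R2
#' per fold with their mean and SD. Out-of-sample R2 is
#' `1 - SSE / sum((y_test - mean(y_train))^2)` and can be negative.
#'
#' @param design Training design matrix.
#' @param y Outcome on the raw scale.
#' @param transform As in [fit_normative_model()].
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed (mandatory).
#' @return List with `rmse` / `r2` fold vectors and `rmse_mean`,
#'   `rmse_sd`, `r2_mean`, `r2_sd`, `folds`.
#' @export
crossvalidate <- function(design, y, transform = c("identity", "log10"),
                          k_folds = 10L, seed) {
  stopifnot(inherits(design, "design_matrix"))
  transform <- match.arg(transform)
  x <- design$x
  n <- nrow(x)
  if (n < k_folds) abort_data("need at least k_folds rows")
  if (transform == "log10") y <- log10(y)
  folds <- withr::with_seed(as.integer(seed),
                            sample(rep_len(seq_len(k_folds), n)))
  xa <- cbind(1, x)
  rmse <- r2 <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    if (sum(tr) <= ncol(xa))
      abort_data("fold ", f, " leaves fewer training rows than predictors")
    fit <- qr(xa[tr, , drop = FALSE])
    if (fit$rank < ncol(xa))
      abort_data("fold ", f, " training design is rank-deficient")
    coefs <- qr.coef(fit, y[tr])
    pred <- as.numeric(xa[!tr, , drop = FALSE] %*% coefs)
    err <- y[!tr] - pred
    rmse[f] <- sqrt(mean(err^2))
    r2[f] <- 1 - sum(err^2) / sum((y[!tr] - mean(y[tr]))^2)
  }
  list(rmse = rmse, r2 = r2,
       rmse_mean = mean(rmse), rmse_sd = stats::sd(rmse),
       r2_mean = mean(r2), r2_sd = stats::sd(r2), folds = folds)
}

#' Standardized coefficients of a fitted norm model
#'
#' `beta_std_j = beta_j * SD(x_j) / SD(y)` on the fitted scale, with the
#' sample SD (`n - 1` denominator) for every column including dummies.
#' The intercept is excluded.
#'
#' @param model A `normative_model`.
#' @return Named numeric vector.
#' @export
standardized_coefficients <- function(model) {
  stopifnot(inherits(model, "normative_model"))
  if (any(model$sds == 0))
    abort_data("zero-variance design column; standardized coefficients undefined")
  model$beta * model$sds / model$sd_y
}

#' Predict a subject's normative volume
#'
#' Evaluates the linear predictor at the subject's covariates (using the
#' training ICV centering) and back-transforms log10-scale models to cm3.
#' Covariates outside the training range of age or ICV trigger a warning,
#' not an error.
#'
#' @param model A `normative_model`.
#' @param newdata Subject table rows.
#' @param scale `"raw"` (cm3; default) or `"model"` (fitted scale).
#' @return Numeric vector of predicted volumes.
#' @export
predict_volume <- function(model, newdata, scale = c("raw", "model")) {
  stopifnot(inherits(model, "normative_model"))
  scale <- match.arg(scale)
  x0 <- score_design(model, newdata)
  out_of_range <- function(col, rng)
    col %in% colnames(x0) &&
      (any(x0[, col] < rng[1] - 1e-9) || any(x0[, col] > rng[2] + 1e-9))
  if (out_of_range("age", model$train_range$age) ||
      out_of_range("icv", model$train_range$icv))
    warning("covariates outside the training range; extrapolating the norm")
  mu <- as.numeric(model$alpha + x0 %*% model$beta)
  if (scale == "raw" && model$transform == "log10") 10^mu else mu
}

#' Age slope of a log-scale model as percent change per year
#'
#' For models fitted on the log10 scale, a per-year slope `b` corresponds
#' to a `(10^b - 1) * 100` percent volume change per year.
#'
#' @param b Slope on the log10 scale.
#' @return Percent change per year.
#' @export
percent_per_year <- function(b) (10^b - 1) * 100

#' Serialize / restore a normative model as JSON
#'
#' Everything needed to score new cases (coefficients, training means and
#' SDs, `R^-1`, transform, `n`, `k`, `s_Vx`, ICV centering) round-trips
#' through a plain JSON file.
#'
#' @param model A `normative_model`.
#' @param path JSON file path.
#' @export
write_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  obj <- model
  obj$Rinv <- unclass(obj$Rinv)
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$beta <- unlist(obj$beta)
  obj$means <- unlist(obj$means)
  obj$sds <- unlist(obj$sds)
  obj$Rinv <- matrix(unlist(obj$Rinv), nrow = obj$k, byrow = FALSE,
                     dimnames = list(names(obj$beta), names(obj$beta)))
  if (is.list(obj$Rinv)) obj$Rinv <- do.call(rbind, obj$Rinv)
  obj$train_range <- lapply(obj$train_range, unlist)
  structure(obj, class = "normative_model")
}
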