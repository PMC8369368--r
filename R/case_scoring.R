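#' Standard error of a predicted volume for a new case
#'
#' The single-case prediction SE
#' \deqn{s_{n+1} = s_{V.x} \sqrt{1 + 1/n + \frac{1}{n-1} z_0' R^{-1} z_0}}
#' where `z_0` holds the subject's predictor values standardized by the
#' training means and SDs (`n - 1` denominator) and `R^-1` is the inverse
#' of the training predictor correlation matrix. The quadratic form
#' expands to the usual sum over diagonal elements `r^ii z_i0^2` plus
#' twice the sum over off-diagonal `r^ij z_i0 z_j0`. This equals the
#' classical prediction SE `s * sqrt(1 + x0'(X'X)^{-1} x0)` of an
#' intercept-augmented OLS fit, which the test suite enforces against an
#' independent hat-matrix oracle.
#'
#' @param model A non-degenerate `normative_model`.
#' @param newdata Subject table rows to score.
#' @return Numeric vector `s_{n+1}`, one per row; always `>= s_Vx`.
#' @export
prediction_se <- function(model, newdata) {
  stopifnot(inherits(model, "normative_model"))
  if (isTRUE(model$degenerate))
    abort_data(model$region,
               ": model is degenerate (s_Vx ~ 0); scoring disabled")
  x0 <- score_design(model, newdata)
  z0 <- sweep(sweep(x0, 2, model$means), 2, model$sds, "/")
  se_new_case(model$sigma, model$n, z0, model$Rinv)
}

# the quadratic-form core of the single-case SE; z0 is a matrix of
# standardized predictor rows
se_new_case <- function(sigma, n, z0, Rinv) {
  quad <- rowSums((z0 %*% Rinv) * z0)
  sigma * sqrt(1 + 1 / n + quad / (n - 1))
}

# accept either a covariate data.frame (rebuilt with the training spec and
# ICV centering) or a ready-made numeric matrix with the model's columns
score_design <- function(model, newdata) {
  if (is.matrix(newdata)) {
    miss <- setdiff(names(model$beta), colnames(newdata))
    if (length(miss))
      abort_data("design matrix lacks column(s): ",
                 paste(miss, collapse = ", "))
    return(newdata[, names(model$beta), drop = FALSE])
  }
  build_design_matrix(newdata, formula_spec(model$variant),
                      icv_center = model$icv_center)$x
}

#' Single-case normative z-scores
#'
#' `z = (V0 - Vhat) / s_{n+1}` on the model's fitted scale: observed
#' volumes of log-scale regions are log10-transformed before differencing.
#' Negative z means the observed volume lies below the norm.
#'
#' @param model A `normative_model`.
#' @param observed Observed raw-scale volumes (cm3), one per row of
#'   `newdata`.
#' @param newdata Subject covariates.
#' @return data.frame with `subject_id`, `region`, `observed`,
#'   `predicted`, `se` and `z` (observed/predicted on the fitted scale).
#' @export
zscore <- function(model, observed, newdata) {
  stopifnot(inherits(model, "normative_model"))
  if (model$transform == "log10") {
    if (any(observed <= 0))
      abort_data(model$region, ": non-positive volume for a log-scale region")
    v0 <- log10(observed)
  } else v0 <- observed
  vhat <- suppressWarnings(predict_volume(model, newdata, scale = "model"))
  se <- prediction_se(model, newdata)
  data.frame(
    subject_id = if ("subject_id" %in% names(newdata))
      as.character(newdata$subject_id) else seq_along(v0),
    region = model$region, observed = v0, predicted = vhat, se = se,
    z = (v0 - vhat) / se, stringsAsFactors = FALSE)
}

#' Score a cohort against a set of norm models
#'
#' @param models Named list of `normative_model`s (from
#'   [fit_region_models()]).
#' @param subjects Subject table to score.
#' @param volumes Row-aligned observed volumes (raw scale).
#' @return Long data.frame of z-scores (one row per subject x region).
#' @export
score_cohort <- function(models, subjects, volumes) {
  out <- lapply(models, function(m) {
    if (!m$region %in% names(volumes))
      abort_data("no observed volumes for region ", m$region)
    zscore(m, volumes[[m$region]], subjects)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Reshape long z-scores to a subject-by-region matrix
#'
#' @param zscores Long table from [score_cohort()].
#' @return data.frame: `subject_id` plus one z column per region.
#' @export
zscore_wide <- function(zscores) {
  wide <- stats::reshape(
    zscores[, c("subject_id", "region", "z")],
    idvar = "subject_id", timevar = "region", direction = "wide")
  names(wide) <- sub("^z\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Group-level z statistics
#'
#' Two modes mirroring the normative validation tables. One-sample mode
#' tests each group's mean z against 0 per region (are controls centered
#' on the norm?). Two-sample mode compares two groups per region with a
#' Welch unequal-variance t-test and reports the mean difference
#' `delta_z = mean(z_A) - mean(z_B)`. Two-sided p-values throughout.
#'
#' @param zscores Long z-score table from [score_cohort()].
#' @param group Factor/character vector aligned with the *subjects* of
#'   `zscores` via `names` or recycled by subject order; easiest is a
#'   named vector `subject_id -> group`.
#' @param mode `"one_sample"` or `"two_sample"`.
#' @param contrast For two-sample mode, `c(A, B)` group labels.
#' @return data.frame with one row per region (and group, in one-sample
#'   mode): mean z / delta z, t, p, and group sizes.
#' @export
group_z_tests <- function(zscores, group,
                          mode = c("one_sample", "two_sample"),
                          contrast = NULL) {
  mode <- match.arg(mode)
  g <- if (!is.null(names(group)))
    unname(group[as.character(zscores$subject_id)])
  else stop("group must be a named vector keyed by subject_id")
  regions <- unique(zscores$region)
  if (mode == "one_sample") {
    grid <- expand.grid(region = regions, group = unique(g),
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      z <- zscores$z[zscores$region == grid$region[i] & g == grid$group[i]]
      if (length(z) < 2) abort_data("group ", grid$group[i],
                                    " has fewer than 2 subjects")
      tt <- safe_t_one(z)
      data.frame(region = grid$region[i], group = grid$group[i],
                 mean_z = mean(z), t = tt$t, p = tt$p, n = length(z),
                 stringsAsFactors = FALSE)
    })
  } else {
    if (is.null(contrast) || length(contrast) != 2)
      abort_config("two_sample mode needs contrast = c(A, B)")
    rows <- lapply(regions, function(reg) {
      za <- zscores$z[zscores$region == reg & g == contrast[1]]
      zb <- zscores$z[zscores$region == reg & g == contrast[2]]
      if (length(za) < 2 || length(zb) < 2)
        abort_data("contrast groups need >= 2 subjects each")
      tt <- safe_t_two(za, zb)
      data.frame(region = reg, group_a = contrast[1], group_b = contrast[2],
                 delta_z = mean(za) - mean(zb), t = tt$t, p = tt$p,
                 n_a = length(za), n_b = length(zb),
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# t-tests guarded for degenerate (zero-variance) inputs: a vector that is
# identically at the null value gives t = 0, p = 1 rather than an error
safe_t_one <- function(z, mu = 0) {
  if (stats::sd(z) == 0) {
    if (mean(z) == mu) return(list(t = 0, p = 1))
    return(list(t = sign(mean(z) - mu) * Inf, p = 0))
  }
  tt <- stats::t.test(z, mu = mu)
  list(t = unname(tt$statistic), p = tt$p.value)
}

safe_t_two <- function(za, zb) {
  if (stats::sd(za) == 0 && stats::sd(zb) == 0) {
    if (mean(za) == mean(zb)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(za) - mean(zb)) * Inf, p = 0))
  }
  tt <- stats::t.test(za, zb)  # Welch unequal-variance
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Select discriminative regions from a delta-z table
#'
#' Applies the rule used to pick classifier features: a region qualifies
#' when *all four* AD-vs-CN delta-z contrasts (after ethnicity adjustment)
#' are strictly below the threshold. Ventricular enlargement (positive
#' delta z) is excluded automatically by the sign of the rule.
#'
#' @param delta_z data.frame with a `region` column and exactly the four
#'   contrast columns named in `contrasts`.
#' @param contrasts Column names of the four contrasts.
#' @param threshold Strict upper bound (default -1).
#' @return Character vector of qualifying region ids, in table order.
#' @export
select_discriminative_regions <- function(delta_z,
                                          contrasts = c("after_kk", "after_ck",
                                                        "after_kc", "after_cc"),
                                          threshold = -1) {
  miss <- setdiff(c("region", contrasts), names(delta_z))
  if (length(miss))
    abort_data("delta-z table is missing contrast column(s): ",
               paste(miss, collapse = ", "))
  m <- as.matrix(delta_z[, contrasts])
  if (any(!is.finite(m))) abort_data("delta-z table contains missing values")
  delta_z$region[rowSums(m < threshold) == length(contrasts)]
}
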