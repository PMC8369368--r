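#' Classifier specification
#'
#' @param features Region ids whose z-scores feed the logistic classifier;
#'   default: the six AD-vulnerable regions from [classifier_regions()].
#' @param k_folds Cross-validation folds for out-of-fold probabilities.
#' @param seed Integer seed for the fold partition.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(features = classifier_regions(),
                            k_folds = 10L, seed = 1L) {
  if (length(features) == 0) abort_config("feature set must be non-empty")
  structure(list(features = features, k_folds = as.integer(k_folds),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped), from "call everything negative" to "call everything
#' positive". Sensitivity and specificity are monotone along the sweep.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels 0/1 (or two-level) outcome.
#' @return data.frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2) abort_data("need both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  grp <- !duplicated(s)
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(which(grp)[-1] - 1L, length(s))  # last index of each tie group
  data.frame(
    threshold = c(Inf, s[keep]),
    sensitivity = c(0, tp[keep] / sum(y)),
    specificity = c(1, 1 - fp[keep] / sum(1 - y)))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the empirical ROC; tied scores contribute
#' the trapezoid between their group boundaries, which is equivalent to
#' the rank-midpoint (Mann-Whitney) convention.
#'
#' @param scores,labels As in [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  fpr <- 1 - rc$specificity
  sum(diff(fpr) * (rc$sensitivity[-1] + rc$sensitivity[-nrow(rc)]) / 2)
}

# fast AUC via the rank statistic; used inside the bootstrap loop where
# the trapezoid construction would dominate runtime (identical value)
auc_rank <- function(scores, y1) {
  r <- rank(scores)
  n1 <- sum(y1); n0 <- length(y1) - n1
  (sum(r[y1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated logistic z-score classifier
#'
#' Logistic regression of diagnosis on the feature-region z-scores. The
#' ROC is built from *out-of-fold* predicted probabilities: the fold
#' partition (stratified by class so every training fold sees both
#' classes) is seeded, each fold is predicted from a fit on the others,
#' and the pooled out-of-fold probabilities give an optimism-free AUC.
#' Complete separation in a training fold is tolerated with a warning
#' suppressed — the ranking of scores remains defined.
#'
#' @param z_wide Wide z-score table from [zscore_wide()] (or any
#'   data.frame with the feature columns).
#' @param labels 0/1 or logical diagnosis per row (1 = case).
#' @param spec A [classifier_spec()].
#' @return List of class `roc_result`: `auc`, `roc` (curve), `oof_prob`,
#'   `folds`, `spec`.
#' @export
fit_z_classifier <- function(z_wide, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  miss <- setdiff(spec$features, names(z_wide))
  if (length(miss))
    abort_data("classifier features missing from z table: ",
               paste(miss, collapse = ", "))
  y <- as.integer(labels)
  if (length(unique(y)) != 2) abort_data("need both classes present")
  x <- as.data.frame(z_wide[, spec$features, drop = FALSE])
  n <- nrow(x)
  folds <- integer(n)
  withr::with_seed(spec$seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(spec$k_folds), length(idx)))
    }
  })
  oof <- numeric(n)
  df <- cbind(y = y, x)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                       data = df[tr, , drop = FALSE]))
    oof[!tr] <- suppressWarnings(
      stats::predict(fit, newdata = df[!tr, , drop = FALSE],
                     type = "response"))
  }
  structure(list(auc = roc_auc(oof, y), roc = roc_curve(oof, y),
                 oof_prob = oof, folds = folds, spec = spec),
            class = "roc_result")
}

#' Stratified-bootstrap comparison of two paired AUCs
#'
#' Both score vectors are defined on the same subjects. Resampling is
#' non-parametric and stratified: cases and controls are resampled
#' separately with replacement, preserving the class counts in every
#' replicate; each replicate yields a difference `AUC_a - AUC_b` on the
#' common resampled subjects. The test statistic is
#' `D = (AUC_a - AUC_b) / SD_boot(delta AUC)` with a standard-normal
#' reference and a two-sided p-value. A zero bootstrap SD (e.g. identical
#' score vectors) is guarded as `D = 0, p = 1`.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels 0/1 outcome.
#' @param n_boot Bootstrap replicates (>= 100; default 10000).
#' @param seed Integer seed.
#' @return List of class `auc_comparison`: `auc_a`, `auc_b`, `delta`,
#'   `D`, `p`, `n_boot`, `seed`.
#' @export
compare_auc_bootstrap <- function(scores_a, scores_b, labels,
                                  n_boot = 10000L, seed = 1L) {
  if (n_boot < 100) abort_config("n_boot < 100 gives an unstable SD")
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    abort_data("scores_a, scores_b and labels must be aligned")
  y <- as.integer(labels)
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (!length(i1) || !length(i0)) abort_data("need both classes present")
  auc_a <- roc_auc(scores_a, y)
  auc_b <- roc_auc(scores_b, y)
  delta <- auc_a - auc_b
  deltas <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      y1 <- c(rep(TRUE, length(i1)), rep(FALSE, length(i0)))
      auc_rank(scores_a[idx], y1) - auc_rank(scores_b[idx], y1)
    }, numeric(1))
  })
  sd_boot <- stats::sd(deltas)
  if (sd_boot < 1e-12) {
    D <- 0; p <- 1
  } else {
    D <- delta / sd_boot
    p <- 2 * stats::pnorm(-abs(D))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, delta = delta,
                 D = D, p = p, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("<auc_comparison> AUC_a = %.3f, AUC_b = %.3f, delta = %.3f, D = %.2f, p = %.4g (%d stratified bootstrap replicates)\n",
              x$auc_a, x$auc_b, x$delta, x$D, x$p, x$n_boot))
  invisible(x)
}

#' Crossover validation: ethnicity adjustment and diagnostic power
#'
#' The stress test for norm incompatibility: discriminate one ethnicity's
#' AD patients (Korean) from the other ethnicity's controls (Caucasian),
#' using six-region z-scores computed under the *base* norm (no
#' ethnicity) and under the *final* norm (with ethnicity). Each condition
#' trains the cross-validated logistic classifier; the two out-of-fold
#' score vectors are compared with the stratified-bootstrap AUC test.
#' With a real ethnic offset in the norms, the adjusted condition should
#' dominate (`auc_after > auc_before`).
#'
#' @param models_base,models_final Named lists of `normative_model`s
#'   covering the classifier feature regions (both fitted on CN norms).
#' @param subjects Validation subjects: Korean AD cases and Caucasian CN
#'   controls (rows of other cells are ignored).
#' @param volumes Row-aligned observed volumes.
#' @param spec A [classifier_spec()].
#' @param n_boot,seed Bootstrap settings for the AUC comparison.
#' @return List of class `crossover_result`: `auc_before`, `auc_after`,
#'   `comparison`, `fit_before`, `fit_after`, `labels`, `seed`.
#' @export
run_crossover_validation <- function(models_base, models_final,
                                     subjects, volumes,
                                     spec = classifier_spec(),
                                     n_boot = 10000L, seed = 1L) {
  keep <- (subjects$ethnicity == "Korean" & subjects$diagnosis == "AD") |
          (subjects$ethnicity == "Caucasian" & subjects$diagnosis == "CN")
  if (!any(keep))
    abort_data("no Korean AD / Caucasian CN subjects to validate on")
  subs <- subjects[keep, , drop = FALSE]
  vols <- volumes[keep, , drop = FALSE]
  labels <- as.integer(subs$diagnosis == "AD")

  feats <- spec$features
  miss <- setdiff(feats, intersect(names(models_base), names(models_final)))
  if (length(miss))
    abort_data("norm models missing for feature region(s): ",
               paste(miss, collapse = ", "))

  z_before <- zscore_wide(score_cohort(models_base[feats], subs, vols))
  z_after <- zscore_wide(score_cohort(models_final[feats], subs, vols))

  # one shared fold partition for both conditions: the comparison is
  # paired by subject, so pairing the cross-validation folds as well
  # removes partition noise from the AUC difference
  spec_cv <- spec; spec_cv$seed <- derive_seed(seed, "classifier_folds")
  fit_before <- fit_z_classifier(z_before, labels, spec_cv)
  fit_after <- fit_z_classifier(z_after, labels, spec_cv)

  cmp <- compare_auc_bootstrap(fit_after$oof_prob, fit_before$oof_prob,
                               labels, n_boot = n_boot,
                               seed = derive_seed(seed, "auc_bootstrap"))
  structure(list(auc_before = fit_before$auc, auc_after = fit_after$auc,
                 comparison = cmp, fit_before = fit_before,
                 fit_after = fit_after, labels = labels,
                 z_before = z_before, z_after = z_after,
                 seed = as.integer(seed)),
            class = "crossover_result")
}
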