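# shared fixtures, built once per test run

.fx <- new.env()

fx_config <- function(n = 150L, seed = 42L) {
  cohort_config(n_per_group = n, seed = seed)
}

# ground truth is deterministic given the config; cache it (the reference
# covariate draw is the expensive part)
fx_truth <- function() {
  if (is.null(.fx$truth)) .fx$truth <- default_ground_truth(fx_config())
  .fx$truth
}

# small four-cell cohort with calibrated AD atrophy applied
fx_cohort <- function() {
  if (is.null(.fx$cohort)) {
    cfg <- fx_config()
    subj <- generate_covariates(cfg)
    vols <- generate_volumes(subj, fx_truth(), seed = 7)
    vols <- apply_ad_atrophy(vols, subj, fx_truth(), atrophy_config())
    .fx$cohort <- list(subjects = subj, volumes = vols, config = cfg)
  }
  .fx$cohort
}

# a ground truth with all ethnicity-linked coefficients zeroed
fx_truth_no_ethnicity <- function() {
  if (is.null(.fx$truth0)) {
    truth <- fx_truth()
    for (reg in names(truth$models)) {
      truth$models[[reg]]$beta[c("ethnicity", "eth_age", "eth_sex")] <- 0
    }
    .fx$truth0 <- truth
  }
  .fx$truth0
}

# wrap an arbitrary numeric matrix as a design_matrix object, bypassing
# the cohort covariate structure
custom_design <- function(x) {
  structure(list(x = x, columns = colnames(x),
                 spec = structure(list(variant = "custom",
                                       columns = colnames(x)),
                                  class = "formula_spec"),
                 icv_center = 0),
            class = "design_matrix")
}

# random correlated design + OLS fit wrapped as a normative_model, for
# oracle tests
random_fit <- function(n, k, seed) {
  withr::with_seed(seed, {
    L <- matrix(rnorm(k * k, sd = 0.4), k, k)
    S <- stats::cov2cor(crossprod(L) + diag(k))
    x <- matrix(rnorm(n * k), n, k) %*% chol(S)
    colnames(x) <- paste0("x", seq_len(k))
    y <- rnorm(n) + x %*% rnorm(k)
    list(x = x, y = as.numeric(y),
         model = fit_normative_model(custom_design(x), as.numeric(y),
                                     region = "toy"))
  })
}

# classical prediction SE for a new observation, via the hat matrix of the
# intercept-augmented design: s * sqrt(1 + x0a' (Xa'Xa)^-1 x0a).
# Independent of the package's correlation-matrix formulation.
hat_prediction_se <- function(x, y, x0) {
  xa <- cbind(1, x)
  fit <- stats::lm.fit(xa, y)
  s <- sqrt(sum(fit$residuals^2) / (nrow(xa) - ncol(xa)))
  xtxi <- solve(crossprod(xa))
  x0a <- cbind(1, x0)
  s * sqrt(1 + rowSums((x0a %*% xtxi) * x0a))
}

# brute-force LMG: average incremental R^2 over explicit orderings
lmg_enumerate <- function(x, y, grouping) {
  G <- length(grouping)
  sst <- sum((y - mean(y))^2)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    1 - sum(qr.resid(qr(cbind(1, x[, cols, drop = FALSE])), y)^2) / sst
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  contrib <- stats::setNames(numeric(G), names(grouping))
  orderings <- perms(seq_len(G))
  for (ord in orderings) {
    cols <- character(0)
    prev <- 0
    for (gi in ord) {
      cols <- c(cols, grouping[[gi]])
      cur <- r2(cols)
      contrib[gi] <- contrib[gi] + (cur - prev)
      prev <- cur
    }
  }
  100 * contrib / length(orderings)
}
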