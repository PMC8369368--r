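test_that("design matrix has the fixed column sets and product interactions", {
  co <- fx_cohort()
  dm_final <- build_design_matrix(co$subjects, formula_spec("final"))
  dm_base <- build_design_matrix(co$subjects, formula_spec("base"))
  expect_equal(ncol(dm_final$x), 17)           # 14 beta terms expanded
  expect_equal(length(formula_spec("final")$terms), 14)
  expect_equal(ncol(dm_base$x), 14)            # 11 beta terms expanded
  expect_equal(length(formula_spec("base")$terms), 11)
  expect_false(any(c("ethnicity", "eth_age", "eth_sex") %in%
                     colnames(dm_base$x)))
  # interactions are elementwise products of their parents
  x <- dm_final$x
  expect_equal(x[, "eth_age"], x[, "ethnicity"] * x[, "age"])
  expect_equal(x[, "mfs_icv"], x[, "mfs"] * x[, "icv"])
  expect_equal(x[, "icv2"], x[, "icv"]^2)
  # all-Korean input: ethnicity column all zeros
  kor <- co$subjects[co$subjects$ethnicity == "Korean", ]
  expect_true(all(build_design_matrix(kor,
                                      formula_spec("final"))$x[, "ethnicity"]
                  == 0))
  bad <- co$subjects
  bad$manufacturer[1] <- "Canon"
  expect_error(build_design_matrix(bad, formula_spec("final")),
               "Canon", class = "brainnorm_data_error")
})

test_that("fitting stores a consistent scoring state", {
  co <- fx_cohort()
  cn <- co$subjects$diagnosis == "CN"
  dm <- build_design_matrix(co$subjects[cn, ], formula_spec("final"))
  m <- fit_normative_model(dm, co$volumes$temporal_l[cn], "temporal_l")
  expect_s3_class(m, "normative_model")
  expect_gt(m$sigma, 0)
  # R^-1 is the exact inverse of the training correlation matrix
  expect_lt(max(abs(m$Rinv %*% stats::cor(dm$x) - diag(m$k))), 1e-8)
  expect_lt(max(abs(m$Rinv - t(m$Rinv))), 1e-10)
  # residuals orthogonal to every standardized design column
  res <- co$volumes$temporal_l[cn] -
    predict_volume(m, co$subjects[cn, ], scale = "model")
  zx <- scale(dm$x)
  expect_lt(max(abs(crossprod(zx, res) / length(res))), 1e-6)
})

test_that("rank deficiency is a named error, not silent dropping", {
  co <- fx_cohort()
  kor <- co$subjects[co$subjects$ethnicity == "Korean" &
                       co$subjects$diagnosis == "CN", ]
  dm <- build_design_matrix(kor, formula_spec("final"))
  expect_error(fit_normative_model(dm, co$volumes$brain[
    co$subjects$ethnicity == "Korean" & co$subjects$diagnosis == "CN"]),
    "ethnicity", class = "brainnorm_data_error")
})

test_that("perfect fits are flagged degenerate and refuse scoring", {
  truth <- fx_truth()
  truth$models$brain$sigma <- 0
  subj <- generate_covariates(fx_config(n = 60, seed = 5), diagnoses = "CN")
  vols <- generate_volumes(subj, truth, seed = 6, regions = "brain")
  dm <- build_design_matrix(subj, formula_spec("final"))
  m <- fit_normative_model(dm, vols$brain, "brain")
  expect_true(m$degenerate)
  expect_error(prediction_se(m, subj), class = "brainnorm_data_error")
})

test_that("large-cohort fits recover the generating coefficients", {
  truth <- fx_truth()
  cfg <- cohort_config(n_per_group = 1500, seed = 77)
  subj <- generate_covariates(cfg, diagnoses = "CN")
  vols <- generate_volumes(subj, truth, seed = 78, regions = "temporal_l")
  dm <- build_design_matrix(subj, formula_spec("final"),
                            icv_center = truth$icv_center)
  m <- fit_normative_model(dm, vols$temporal_l, "temporal_l")
  xa <- cbind(1, dm$x)
  se <- m$sigma * sqrt(diag(chol2inv(qr.R(qr(xa)))))
  est <- c(m$alpha, m$beta)
  tru <- c(truth$models$temporal_l$alpha, truth$models$temporal_l$beta)
  expect_true(all(abs(est - tru) < 4 * se))
})

test_that("cross-validation: noiseless, determinism, honest null R2", {
  # noiseless linear outcome: RMSE ~ 0, R2 ~ 1 in every fold
  fit <- random_fit(120, 5, seed = 13)
  dm <- custom_design(fit$x)
  y <- as.numeric(5 + fit$x %*% rep(1, ncol(fit$x)))
  cv <- crossvalidate(dm, y, k_folds = 10, seed = 1)
  expect_lt(cv$rmse_mean, 1e-8)
  expect_equal(cv$r2_mean, 1, tolerance = 1e-10)
  # determinism of the partition and metrics
  cv2 <- crossvalidate(dm, y, k_folds = 10, seed = 1)
  expect_identical(cv$folds, cv2$folds)
  # pure-noise outcome: out-of-sample R2 <= 0 on average (50 replicates)
  r2s <- vapply(seq_len(50), function(i) {
    yn <- withr::with_seed(3000 + i, stats::rnorm(nrow(dm$x)))
    crossvalidate(dm, yn, k_folds = 5, seed = i)$r2_mean
  }, numeric(1))
  expect_lt(mean(r2s), 0)
})

test_that("cross-validated R2 does not beat in-sample R2 on average", {
  diffs <- vapply(seq_len(20), function(i) {
    fit <- random_fit(100, 6, seed = 400 + i)
    dm <- custom_design(fit$x)
    cv <- crossvalidate(dm, fit$y, k_folds = 10, seed = i)
    fit$model$r2 - cv$r2_mean
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("standardized coefficients: closed form and scale invariance", {
  # single informative predictor: beta_std ~ cor(x, y)
  fit <- random_fit(400, 1, seed = 21)
  sc <- standardized_coefficients(fit$model)
  expect_equal(unname(sc), stats::cor(fit$x[, 1], fit$y), tolerance = 1e-10)
  # rescaling a raw covariate leaves standardized coefficients unchanged
  co <- fx_cohort()
  cn <- co$subjects$diagnosis == "CN"
  m1 <- fit_region_models(co$subjects[cn, ], co$volumes[cn, ], "brain")$brain
  subj_mm <- co$subjects
  subj_mm$icv_cm3 <- subj_mm$icv_cm3 * 1000  # cm3 -> mm3
  m2 <- fit_region_models(subj_mm[cn, ], co$volumes[cn, ], "brain")$brain
  expect_equal(standardized_coefficients(m1),
               standardized_coefficients(m2), tolerance = 1e-6)
})

test_that("prediction back-transforms and reports log slopes as % per year", {
  expect_equal(percent_per_year(0.01), (10^0.01 - 1) * 100)
  co <- fx_cohort()
  cn <- co$subjects$diagnosis == "CN"
  m <- fit_region_models(co$subjects[cn, ], co$volumes[cn, ],
                         "ventricle")$ventricle
  expect_equal(m$transform, "log10")
  mu <- predict_volume(m, co$subjects[cn, ][1:5, ], scale = "model")
  expect_equal(predict_volume(m, co$subjects[cn, ][1:5, ]), 10^mu,
               tolerance = 1e-10)
  # two subjects identical except ethnicity: prediction gap = ethnicity
  # main effect + interaction contributions (linearity)
  s2 <- co$subjects[cn, ][c(1, 1), ]
  s2$ethnicity <- c("Korean", "Caucasian")
  mb <- fit_region_models(co$subjects[cn, ], co$volumes[cn, ],
                          "temporal_l")$temporal_l
  gap <- diff(predict_volume(mb, s2))
  expected <- mb$beta[["ethnicity"]] + mb$beta[["eth_age"]] * s2$age[1] +
    mb$beta[["eth_sex"]] * (s2$sex[1] == "M")
  expect_equal(gap, expected, tolerance = 1e-10)
})

test_that("model JSON serialization round-trips scoring exactly", {
  co <- fx_cohort()
  cn <- co$subjects$diagnosis == "CN"
  m <- fit_region_models(co$subjects[cn, ], co$volumes[cn, ],
                         "hippocampus_l")$hippocampus_l
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_model(m, path)
  m2 <- read_normative_model(path)
  probe <- co$subjects[1:10, ]
  expect_equal(prediction_se(m2, probe), prediction_se(m, probe),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(predict_volume(m2, probe), predict_volume(m, probe),
               tolerance = 1e-12)
})
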