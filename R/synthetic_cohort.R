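#' Configuration for the synthetic cohort generator
#'
#' Describes the demographic and technical structure of the simulated
#' cohorts: two ethnic groups (Korean, Caucasian), age 59-89 with a
#' truncated-normal distribution (mean 73, SD 6) by default, per-ethnicity
#' sex ratio and 1.5T/3T mix, per-ethnicity scanner-manufacturer mix
#' (the Korean sample is Siemens-only; the Caucasian sample is multi-site),
#' and per sex-by-ethnicity ICV means. Defaults emulate the published
#' cohort structure of large elderly Korean / Caucasian normative samples.
#'
#' @param n_per_group Subjects per ethnicity-by-diagnosis cell (>= 2).
#' @param age_range Two-element numeric within \[59, 89\].
#' @param age_dist `"truncnorm"` (default) or `"uniform"`.
#' @param age_mean,age_sd Moments of the (pre-truncation) age normal.
#' @param prop_female Named fractions per ethnicity.
#' @param prop_3T Named fractions per ethnicity.
#' @param manufacturer_probs Named list per ethnicity of probability
#'   vectors over `c(Siemens, GE, Philips)`.
#' @param icv_mean Named list per ethnicity of `c(F=, M=)` ICV means, cm3.
#' @param icv_sd ICV standard deviation within each cell, cm3.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 210,
                          age_range = c(59, 89),
                          age_dist = c("truncnorm", "uniform"),
                          age_mean = 73, age_sd = 6,
                          prop_female = c(Korean = 0.62, Caucasian = 0.55),
                          prop_3T = c(Korean = 0.81, Caucasian = 0.77),
                          manufacturer_probs = list(
                            Korean    = c(Siemens = 1,   GE = 0,    Philips = 0),
                            Caucasian = c(Siemens = 0.5, GE = 0.25, Philips = 0.25)),
                          icv_mean = list(Korean = c(F = 1320, M = 1490),
                                          Caucasian = c(F = 1360, M = 1540)),
                          icv_sd = 110,
                          seed = 1L) {
  age_dist <- match.arg(age_dist)
  if (!is.numeric(n_per_group) || n_per_group < 2)
    abort_config("n_per_group must be >= 2")
  if (length(age_range) != 2 || age_range[1] < 59 || age_range[2] > 89 ||
      age_range[1] >= age_range[2])
    abort_config("age_range must be an increasing pair within [59, 89]")
  for (e in c("Korean", "Caucasian")) {
    check_prob_vector(c(prop_female[[e]], 1 - prop_female[[e]]),
                      paste0("prop_female[", e, "]"))
    check_prob_vector(c(prop_3T[[e]], 1 - prop_3T[[e]]),
                      paste0("prop_3T[", e, "]"))
    check_prob_vector(manufacturer_probs[[e]],
                      paste0("manufacturer_probs[", e, "]"))
    if (icv_sd <= 0 || any(icv_mean[[e]] <= 0))
      abort_config("ICV means and SD must be positive")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 age_range = as.numeric(age_range), age_dist = age_dist,
                 age_mean = age_mean, age_sd = age_sd,
                 prop_female = prop_female, prop_3T = prop_3T,
                 manufacturer_probs = manufacturer_probs,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# inverse-CDF truncated normal draw (vectorized, one uniform per subject)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate subject covariates
#'
#' Draws one row per subject for each requested ethnicity-by-diagnosis
#' cell. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param ethnicities,diagnoses Cells to generate (crossed).
#' @param n_per_group Override of `config$n_per_group`; scalar or named by
#'   `"<ethnicity>.<diagnosis>"`.
#' @return A subject data.frame with columns `subject_id`, `ethnicity`,
#'   `diagnosis`, `age`, `sex`, `icv_cm3`, `mfs`, `manufacturer`.
#' @export
generate_covariates <- function(config,
                                ethnicities = c("Korean", "Caucasian"),
                                diagnoses = c("CN", "AD"),
                                n_per_group = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n_per_group <- n_per_group %||% config$n_per_group
  cells <- expand.grid(diagnosis = diagnoses, ethnicity = ethnicities,
                       stringsAsFactors = FALSE)[, c(2, 1)]
  withr::with_seed(config$seed, {
    out <- lapply(seq_len(nrow(cells)), function(i) {
      eth <- cells$ethnicity[i]; dx <- cells$diagnosis[i]
      key <- paste(eth, dx, sep = ".")
      n <- if (length(n_per_group) > 1) n_per_group[[key]] else n_per_group
      n <- as.integer(n)
      age <- if (config$age_dist == "uniform")
        stats::runif(n, config$age_range[1], config$age_range[2])
      else
        rtruncnorm(n, config$age_mean, config$age_sd,
                   config$age_range[1], config$age_range[2])
      sex <- ifelse(stats::runif(n) < config$prop_female[[eth]], "F", "M")
      mfs <- ifelse(stats::runif(n) < config$prop_3T[[eth]], "3", "1.5")
      man <- sample(c("Siemens", "GE", "Philips"), n, replace = TRUE,
                    prob = config$manufacturer_probs[[eth]])
      icv <- stats::rnorm(n, config$icv_mean[[eth]][sex], config$icv_sd)
      icv <- pmax(icv, 800)  # guard: ICV must stay physically positive
      data.frame(subject_id = sprintf("%s_%s_%04d", substr(eth, 1, 3), dx,
                                      seq_len(n)),
                 ethnicity = eth, diagnosis = dx, age = age, sex = sex,
                 icv_cm3 = icv, mfs = mfs, manufacturer = man,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

read_calibration <- function(file) {
  path <- system.file("extdata", file, package = "brainnorm")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Reference delta-z table for the four AD-vs-CN contrasts
#'
#' The transcribed per-region mean z differences (AD minus CN) for the
#' contrasts Kor.AD vs Kor.CN (`kk`), Cau.AD vs Kor.CN (`ck`), Kor.AD vs
#' Cau.CN (`kc`) and Cau.AD vs Cau.CN (`cc`), before and after ethnicity
#' adjustment, from published multi-ethnic elderly norms. Calibrates the
#' default synthetic atrophy and feeds the discriminative-region rule.
#'
#' @return data.frame with `region` plus eight `before_*` / `after_*`
#'   delta-z columns.
#' @export
delta_z_reference <- function() read_calibration("delta_z_reference.csv")

#' Ground-truth generative model for synthetic volumes
#'
#' Builds the per-region linear models the synthetic generator draws from.
#' Shipped standardized coefficients (typical of published multi-ethnic
#' elderly norms) are rescaled to raw units as
#' `beta_j = beta_std_j * SD(y) / SD(x_j)`, where the design-column SDs are
#' measured on a large internally-seeded covariate draw under `config` and
#' `SD(y) = RMSE / sqrt(1 - R2)`. The residual SD is the shipped RMSE
#' (log10 units for ventricular regions). Intercepts anchor the predicted
#' volume at the covariate means to the registry's nominal region means.
#' Raw-scale fidelity is not claimed; effect *directions* and relative
#' magnitudes follow the calibration table.
#'
#' @param config A [cohort_config()]; only its covariate structure is used
#'   (the reference draw uses a fixed internal seed, so the ground truth is
#'   a deterministic function of the configuration).
#' @param regions Region registry subset to include.
#' @param n_ref Size of the internal reference covariate draw.
#' @return Object of class `ground_truth`: `spec`, `icv_center`, and a per
#'   region list with `alpha`, `beta` (named, raw scale), `sigma`,
#'   `log_scale`.
#' @export
default_ground_truth <- function(config = cohort_config(),
                                 regions = norm_regions(),
                                 n_ref = 20000L) {
  calib <- read_calibration("std_coef_calibration.csv")
  spec <- formula_spec("final")
  ref_cfg <- config
  ref_cfg$seed <- 20110613L  # fixed internal seed for the reference draw
  ref_cfg$n_per_group <- as.integer(ceiling(n_ref / 2))
  ref <- generate_covariates(ref_cfg, diagnoses = "CN")
  dm <- build_design_matrix(ref, spec)
  sds <- col_sds(dm$x)
  xbar <- colMeans(dm$x)

  models <- lapply(seq_len(nrow(regions)), function(i) {
    reg <- regions$region[i]
    row <- calib[calib$region == reg, , drop = FALSE]
    if (nrow(row) != 1L)
      abort_data("region not covered by calibration table: ", reg)
    sd_y <- row$rmse / sqrt(1 - row$r2)
    beta_std <- as.numeric(row[, spec$columns])
    beta <- beta_std * sd_y / sds
    names(beta) <- spec$columns
    alpha <- regions$mean_volume[i] - sum(beta * xbar)
    list(region = reg, alpha = alpha, beta = beta, sigma = row$rmse,
         log_scale = regions$log_scale[i])
  })
  names(models) <- regions$region
  structure(list(spec = spec, icv_center = dm$icv_center, models = models),
            class = "ground_truth")
}

#' Generate per-region volumes from a ground-truth model
#'
#' Computes `V = alpha + x'beta + eps`, `eps ~ N(0, sigma^2)`, on the
#' model scale of each region; log-scale regions are generated on log10
#' scale and back-transformed, so their volumes are strictly positive.
#' Deterministic given `seed`.
#'
#' @param subjects Subject table from [generate_covariates()].
#' @param truth A [default_ground_truth()] object (or one with modified
#'   coefficients / residual SDs).
#' @param seed Integer seed.
#' @param regions Region ids to generate (default: all in `truth`).
#' @return data.frame: `subject_id` plus one numeric column per region
#'   (cm3 on the raw scale for all regions).
#' @export
generate_volumes <- function(subjects, truth, seed,
                             regions = names(truth$models)) {
  stopifnot(inherits(truth, "ground_truth"))
  check_subjects(subjects)
  miss <- setdiff(regions, names(truth$models))
  if (length(miss))
    abort_data("regions missing from ground truth: ",
               paste(miss, collapse = ", "))
  dm <- build_design_matrix(subjects, truth$spec,
                            icv_center = truth$icv_center)
  n <- nrow(dm$x)
  withr::with_seed(as.integer(seed), {
    vols <- lapply(regions, function(reg) {
      m <- truth$models[[reg]]
      mu <- as.numeric(m$alpha + dm$x %*% m$beta)
      v <- mu + stats::rnorm(n, 0, m$sigma)
      if (m$log_scale) 10^v else v
    })
    names(vols) <- regions
    cbind(data.frame(subject_id = subjects$subject_id,
                     stringsAsFactors = FALSE),
          as.data.frame(vols))
  })
}

#' Configuration of synthetic AD atrophy
#'
#' Per-region effect sizes in units of the ground-truth residual SD on the
#' model scale (negative = atrophy; positive = enlargement, used for the
#' ventricles). Regions not listed default to 0. The default effects are
#' the after-adjustment Kor.AD vs Kor.CN column of [delta_z_reference()],
#' so a synthetic AD group reproduces the published z-score separation
#' pattern: atrophy concentrated in temporal cortex, hippocampus and
#' amygdala, with ventricular enlargement.
#'
#' @param effects Named numeric vector of effect sizes, or `NULL` for the
#'   calibrated defaults.
#' @param seed Retained for interface symmetry; the shift itself is
#'   deterministic.
#' @return Object of class `atrophy_config`.
#' @export
atrophy_config <- function(effects = NULL, seed = 1L) {
  if (is.null(effects)) {
    ref <- delta_z_reference()
    effects <- stats::setNames(ref$after_kk, ref$region)
  }
  if (is.null(names(effects)) || any(!nzchar(names(effects))))
    abort_config("atrophy effects must be a named vector of region ids")
  structure(list(effects = effects, seed = as.integer(seed)),
            class = "atrophy_config")
}

#' Apply AD atrophy to a synthetic volume table
#'
#' Shifts the volumes of AD-diagnosed subjects by
#' `effect_size * residual SD` on the model scale of each region (log10
#' scale for ventricular regions, i.e. a multiplicative change in cm3);
#' CN rows are returned unchanged.
#'
#' @param volumes Volume table from [generate_volumes()].
#' @param subjects Matching subject table (provides `diagnosis`).
#' @param truth The ground truth that generated `volumes` (provides the
#'   per-region residual SDs and scale flags).
#' @param atrophy An [atrophy_config()].
#' @return Volume table of the same shape.
#' @export
apply_ad_atrophy <- function(volumes, subjects, truth,
                             atrophy = atrophy_config()) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(atrophy, "atrophy_config"))
  if (!"diagnosis" %in% names(subjects))
    abort_data("subject table has no diagnosis column")
  if (!identical(as.character(volumes$subject_id),
                 as.character(subjects$subject_id)))
    abort_data("volumes and subjects must be row-aligned by subject_id")
  ad <- subjects$diagnosis == "AD"
  out <- volumes
  for (reg in intersect(names(volumes), names(truth$models))) {
    eff <- if (reg %in% names(atrophy$effects))
      atrophy$effects[[reg]] else 0
    if (is.na(eff) || eff == 0 || !any(ad)) next
    m <- truth$models[[reg]]
    if (m$log_scale) {
      out[[reg]][ad] <- 10^(log10(out[[reg]][ad]) + eff * m$sigma)
    } else {
      out[[reg]][ad] <- out[[reg]][ad] + eff * m$sigma
    }
  }
  out
}

#' Write / read a cohort CSV
#'
#' The interchange format of the pipeline: one row per subject, fixed
#' covariate columns then one column per region, with the generating seed
#' recorded in a `# seed: <n>` header comment.
#'
#' @param subjects,volumes Row-aligned covariate and volume tables.
#' @param path Output file.
#' @param seed Seed to record in the header.
#' @export
write_cohort_csv <- function(subjects, volumes, path, seed = NA) {
  stopifnot(identical(as.character(subjects$subject_id),
                      as.character(volumes$subject_id)))
  df <- cbind(subjects, volumes[, setdiff(names(volumes), "subject_id"),
                                drop = FALSE])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @return `read_cohort_csv`: list with `subjects`, `volumes`, `seed`.
#' @export
read_cohort_csv <- function(path) {
  first <- readLines(path, n = 1L)
  seed <- if (startsWith(first, "# seed:"))
    suppressWarnings(as.integer(trimws(sub("# seed:", "", first)))) else NA
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  covs <- intersect(required_covariates(), names(df))
  regs <- setdiff(names(df), covs)
  list(subjects = df[, covs, drop = FALSE],
       volumes = cbind(df[, "subject_id", drop = FALSE],
                       df[, regs, drop = FALSE]),
       seed = seed)
}
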