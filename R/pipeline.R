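#' Pipeline configuration
#'
#' One object carrying every knob of the end-to-end run: cohort sizes,
#' per-stage seeds (derived deterministically from one master seed),
#' regions to model, classifier features, and bootstrap settings.
#'
#' @param seed Master seed; every stochastic stage uses a distinct stream
#'   derived from it.
#' @param n_norm CN subjects per ethnicity in the norm-fitting cohort.
#' @param n_per_group Subjects per ethnicity-by-diagnosis cell in the
#'   validation cohort (pre-matching).
#' @param regions Region ids to model (default: full registry).
#' @param features Classifier feature regions.
#' @param n_boot Bootstrap replicates for the AUC comparison.
#' @param cohort Base [cohort_config()] template for covariate structure.
#' @param atrophy An [atrophy_config()]; defaults to calibrated AD effects.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_norm = 600L, n_per_group = 210L,
                            regions = norm_regions()$region,
                            features = classifier_regions(),
                            n_boot = 10000L,
                            cohort = cohort_config(),
                            atrophy = atrophy_config()) {
  if (is.null(seed) || is.na(seed))
    abort_config("a master seed is required")
  if (!all(features %in% regions))
    abort_config("classifier features must be among the modeled regions")
  structure(list(seed = as.integer(seed), n_norm = as.integer(n_norm),
                 n_per_group = as.integer(n_per_group), regions = regions,
                 features = features, n_boot = as.integer(n_boot),
                 cohort = cohort, atrophy = atrophy),
            class = "pipeline_config")
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full normative-modeling pipeline
#'
#' Executes simulate -> match -> fit (base and final) -> cross-validate ->
#' standardized coefficients -> variance decomposition -> z-scoring and
#' group tests -> discriminative-region selection -> crossover AUC
#' validation, writing every intermediate artifact as CSV/JSON into
#' `out_dir` plus a manifest of file hashes and the seeds used. The run is
#' a pure function of the config: identical configs give byte-identical
#' output directories.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest path.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)))
    abort_config("out_dir exists and is not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  written <- character(0)
  keep <- function(path) { written <<- c(written, path); path }

  ## -- simulate ------------------------------------------------------
  truth <- default_ground_truth(config$cohort)
  norm_cfg <- config$cohort
  norm_cfg$seed <- derive_seed(config$seed, "norm_covariates")
  norm_subj <- generate_covariates(norm_cfg, diagnoses = "CN",
                                   n_per_group = config$n_norm)
  norm_vols <- generate_volumes(norm_subj, truth,
                                derive_seed(config$seed, "norm_volumes"),
                                regions = config$regions)
  val_cfg <- config$cohort
  val_cfg$seed <- derive_seed(config$seed, "val_covariates")
  val_subj <- generate_covariates(val_cfg, n_per_group = config$n_per_group)
  val_vols <- generate_volumes(val_subj, truth,
                               derive_seed(config$seed, "val_volumes"),
                               regions = config$regions)
  val_vols <- apply_ad_atrophy(val_vols, val_subj, truth, config$atrophy)
  keep(write_cohort_csv(norm_subj, norm_vols, p("norm_cohort.csv"),
                        seed = norm_cfg$seed))
  keep(write_cohort_csv(val_subj, val_vols, p("validation_cohort.csv"),
                        seed = val_cfg$seed))

  ## -- match ---------------------------------------------------------
  matched <- match_four_groups(val_subj,
                               match_spec(seed = derive_seed(config$seed,
                                                             "matching")))
  matched_subj <- do.call(rbind, c(matched$groups,
                                   list(make.row.names = FALSE)))
  matched_vols <- val_vols[match(matched_subj$subject_id,
                                 val_vols$subject_id), , drop = FALSE]
  rownames(matched_vols) <- NULL
  keep(write_cohort_csv(matched_subj, matched_vols, p("matched_cohort.csv"),
                        seed = config$seed))
  keep(write_csv_out(do.call(rbind, c(lapply(names(matched$balance),
    function(g) cbind(group = g, matched$balance[[g]])),
    list(make.row.names = FALSE))), p("matching_balance.csv")))

  ## -- fit (both variants) + CV + standardized coefficients ----------
  models <- list(
    base = fit_region_models(norm_subj, norm_vols, config$regions, "base"),
    final = fit_region_models(norm_subj, norm_vols, config$regions, "final"))
  dir.create(p("models"), showWarnings = FALSE)
  for (v in names(models)) for (m in models[[v]])
    keep(write_normative_model(m, p("models/", v, "_", m$region, ".json")))

  reg_tab <- norm_regions()
  cv_rows <- list(); sc_rows <- list()
  for (v in names(models)) {
    dm <- build_design_matrix(norm_subj, formula_spec(v))
    for (reg in config$regions) {
      lg <- isTRUE(reg_tab$log_scale[match(reg, reg_tab$region)])
      cv <- crossvalidate(dm, norm_vols[[reg]],
                          transform = if (lg) "log10" else "identity",
                          k_folds = 10L,
                          seed = derive_seed(config$seed,
                                             paste0("cv_", v, "_", reg)))
      cv_rows[[paste(v, reg)]] <- data.frame(
        variant = v, region = reg, rmse_mean = cv$rmse_mean,
        rmse_sd = cv$rmse_sd, r2_mean = cv$r2_mean, r2_sd = cv$r2_sd)
      sc <- standardized_coefficients(models[[v]][[reg]])
      sc_rows[[paste(v, reg)]] <- cbind(
        data.frame(variant = v, region = reg), as.data.frame(as.list(sc)))
    }
  }
  keep(write_csv_out(do.call(rbind, c(cv_rows, list(make.row.names = FALSE))),
                     p("cv_metrics.csv")))
  sc_tab <- do.call(rbind, c(lapply(sc_rows[grep("^final", names(sc_rows))],
                                    identity), list(make.row.names = FALSE)))
  keep(write_csv_out(sc_tab, p("standardized_coefficients.csv")))

  ## -- variance decomposition ---------------------------------------
  keep(write_csv_out(relative_importance_table(norm_subj, norm_vols,
                                               config$regions, "final"),
                     p("relative_importance.csv")))

  ## -- z-scores and group tests --------------------------------------
  zs <- list(before = score_cohort(models$base, matched_subj, matched_vols),
             after = score_cohort(models$final, matched_subj, matched_vols))
  grp <- stats::setNames(paste(matched_subj$ethnicity,
                               matched_subj$diagnosis, sep = "."),
                         matched_subj$subject_id)
  cn_tests <- list(); dz_tests <- list()
  contrasts <- list(kk = c("Korean.AD", "Korean.CN"),
                    ck = c("Caucasian.AD", "Korean.CN"),
                    kc = c("Korean.AD", "Caucasian.CN"),
                    cc = c("Caucasian.AD", "Caucasian.CN"))
  for (w in names(zs)) {
    keep(write_csv_out(zs[[w]], p("zscores_", w, ".csv")))
    cn <- zs[[w]][grp[as.character(zs[[w]]$subject_id)] %in%
                    c("Korean.CN", "Caucasian.CN"), ]
    cn_tests[[w]] <- cbind(adjustment = w,
                           group_z_tests(cn, grp, "one_sample"))
    for (cname in names(contrasts)) {
      tt <- group_z_tests(zs[[w]], grp, "two_sample",
                          contrast = contrasts[[cname]])
      dz_tests[[paste(w, cname)]] <- cbind(adjustment = w,
                                           contrast = cname, tt)
    }
  }
  keep(write_csv_out(do.call(rbind, c(cn_tests,
                                      list(make.row.names = FALSE))),
                     p("cn_z_tests.csv")))
  dz_tab <- do.call(rbind, c(dz_tests, list(make.row.names = FALSE)))
  keep(write_csv_out(dz_tab, p("delta_z_tests.csv")))

  ## -- discriminative-region selection -------------------------------
  dz_after <- dz_tab[dz_tab$adjustment == "after", ]
  dz_wide <- stats::reshape(
    dz_after[, c("region", "contrast", "delta_z")],
    idvar = "region", timevar = "contrast", direction = "wide")
  names(dz_wide) <- sub("^delta_z\\.", "after_", names(dz_wide))
  candidates <- dz_wide[!dz_wide$region %in%
                          reg_tab$region[reg_tab$aggregate], ]
  selected <- select_discriminative_regions(candidates)
  keep(writeLines2(selected, p("selected_regions.txt")))

  ## -- crossover validation ------------------------------------------
  crossover <- run_crossover_validation(
    models$base, models$final, matched_subj, matched_vols,
    classifier_spec(features = config$features),
    n_boot = config$n_boot,
    seed = derive_seed(config$seed, "crossover"))
  cmp <- crossover$comparison
  keep(p("auc_comparison.json"))
  jsonlite::write_json(
    list(auc_before = crossover$auc_before,
         auc_after = crossover$auc_after,
         delta = cmp$delta, D = cmp$D, p = cmp$p,
         n_boot = cmp$n_boot, seed = cmp$seed),
    p("auc_comparison.json"), auto_unbox = TRUE, digits = NA)
  keep(write_csv_out(cbind(condition = "before", crossover$fit_before$roc),
                     p("roc_before.csv")))
  keep(write_csv_out(cbind(condition = "after", crossover$fit_after$roc),
                     p("roc_after.csv")))

  ## -- summary + manifest --------------------------------------------
  summary_lines <- c(
    "brainnorm pipeline summary",
    sprintf("master seed: %d", config$seed),
    sprintf("norm cohort: %d CN per ethnicity; validation: %d per cell; matched n per group: %d (anchor %s)",
            config$n_norm, config$n_per_group, matched$n, matched$anchor),
    sprintf("regions modeled: %d; classifier features: %s",
            length(config$regions), paste(config$features, collapse = ", ")),
    sprintf("selected discriminative regions (all four after-adjustment delta-z < -1): %s",
            paste(selected, collapse = ", ")),
    sprintf("crossover Korean AD vs Caucasian CN: AUC before = %.3f, after = %.3f, delta = %.3f, D = %.2f, p = %.3g",
            crossover$auc_before, crossover$auc_after, cmp$delta, cmp$D,
            cmp$p))
  keep(writeLines2(summary_lines, p("summary.txt")))

  rel <- sort(substring(written, nchar(out_dir) + 2))
  manifest <- data.frame(
    file = rel,
    md5 = unname(tools::md5sum(file.path(out_dir, rel))),
    stringsAsFactors = FALSE)
  write_csv_out(manifest, p("manifest.csv"))

  invisible(list(models = models, matched = matched, crossover = crossover,
                 selected = selected, delta_z = dz_tab,
                 manifest = p("manifest.csv"), out_dir = out_dir))
}

writeLines2 <- function(lines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  path
}
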