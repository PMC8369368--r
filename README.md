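# brainnorm

Normative modeling of lobar and subcortical brain volumes in old age,
across ethnic groups.

## Why

Clinical use of regional brain volumetry needs a *norm*: the volume
expected for a person of a given age, sex, head size and scanner, against
which a patient's measured volume becomes a z-score. Published norms come
almost entirely from Caucasian cohorts, but elderly East Asians and
Caucasians differ systematically in regional volumes even after
intracranial-volume adjustment — and the difference is largest in exactly
the regions where Alzheimer's disease (AD) atrophy shows (temporal
cortex, hippocampus, amygdala). Scored against a Caucasian norm, a Korean
AD patient's atrophied regions can still look "normal". This package
implements the machinery to quantify and correct that: ethnicity-aware
norm regressions, single-case z-scores, variance decomposition,
propensity-matched validation groups, and a bootstrap test of how much
the ethnicity adjustment improves diagnostic discrimination. A synthetic
cohort generator emulating the statistical structure of large Korean /
Caucasian elderly samples makes the entire pipeline testable without
access to restricted data.

## The model

Per region (volume in cm³; log₁₀ cm³ for ventricles), ordinary least
squares:

    V̂ = β₁·ethnicity + β₂·age + β₃·sex + β₄·ICV + β₅·ICV² + β₆·ICV³
        + β₇·MFS + β₈·manufacturer + β₉·ethnicity×age + β₁₀·ethnicity×sex
        + β₁₁·sex×age + β₁₂·MFS×manufacturer + β₁₃·MFS×ICV
        + β₁₄·ICV×manufacturer + α

(the *base* variant drops the three ethnicity terms). A new subject is
scored with the single-case prediction SE (Crawford–Garthwaite):

    s_{n+1} = s_{V·x} · sqrt(1 + 1/n + z₀' R⁻¹ z₀ / (n−1)),
    z = (V₀ − V̂) / s_{n+1}

where `R⁻¹` is the inverse training predictor correlation matrix and
`z₀` the subject's standardized predictor values. This equals the
classical prediction SE `s·sqrt(1 + x₀'(X'X)⁻¹x₀)`, which the test suite
enforces against an independent hat-matrix oracle. Per-predictor
importance is the orderings-averaged R² decomposition (LMG); the
diagnostic validation trains a six-region z-score logistic classifier and
compares AUCs before/after ethnicity adjustment with a stratified
bootstrap (`D = ΔAUC / SD_boot`).

## Worked example

```r
library(brainnorm)

cfg      <- cohort_config(n_per_group = 210, seed = 2026)
truth    <- default_ground_truth(cfg)
subjects <- generate_covariates(cfg)                  # 4 x 210 subjects
volumes  <- generate_volumes(subjects, truth, seed = 1)
volumes  <- apply_ad_atrophy(volumes, subjects, truth, atrophy_config())

cn     <- subjects$diagnosis == "CN"
models <- fit_region_models(subjects[cn, ], volumes[cn, ],
                            c("hippocampus_l", "temporal_l", "ventricle"))
models$hippocampus_l
#> <normative_model> hippocampus_l (final variant, identity scale):
#>   n = 420, k = 17, s_Vx = 0.3998, R2 = 0.405

zs  <- score_cohort(models, subjects, volumes)
grp <- setNames(paste(subjects$ethnicity, subjects$diagnosis, sep = "."),
                subjects$subject_id)
group_z_tests(zs, grp, "two_sample", contrast = c("Korean.AD", "Korean.CN"))
#>          region   group_a   group_b delta_z     t        p n_a n_b
#> 1 hippocampus_l Korean.AD Korean.CN  -1.549 -16.6 9.70e-48 210 210
#> 2    temporal_l Korean.AD Korean.CN  -1.575 -15.7 4.00e-44 210 210
#> 3     ventricle Korean.AD Korean.CN   0.969  10.1 1.19e-21 210 210
```

Korean AD patients sit ~1.5 SD below their norm in hippocampus and
temporal cortex and ~1 SD above it in ventricular volume — the calibrated
atrophy pattern the generator encodes. The crossover stress test
(classify Korean AD patients against *Caucasian* controls) shows what the
ethnicity adjustment buys:

```r
mb <- fit_region_models(subjects[cn, ], volumes[cn, ], classifier_regions(), "base")
mf <- fit_region_models(subjects[cn, ], volumes[cn, ], classifier_regions(), "final")
run_crossover_validation(mb, mf, subjects, volumes,
                         n_boot = 2000, seed = 7)$comparison
#> <auc_comparison> AUC_a = 0.989, AUC_b = 0.925, delta = 0.065, D = 6.29,
#>   p = 3.219e-10 (2000 stratified bootstrap replicates)
```

Without the ethnicity terms the classifier loses discrimination
(AUC 0.925 vs 0.989) because the Korean patients' larger baseline
volumes mask their atrophy against the Caucasian norm; the stratified
bootstrap calls the AUC difference highly significant.

## Command line

An executable `brainnorm` is installed under the package's `exec/`
directory (subcommands `simulate`, `fit`, `score`, `importance`, `match`,
`validate`, `run-all`; common flags `--seed`, `--config`, `--out`; exit
codes 0 / 2 config error / 3 data error):

```sh
brainnorm run-all --seed 17 --out run_dir
```

`run-all` writes every intermediate CSV/JSON plus a manifest of MD5
hashes; identical configs give byte-identical run directories.

## Layout

- `R/` — generator, design/fit, scoring, LMG decomposition, matching,
  ROC/bootstrap, pipeline and CLI
- `inst/extdata/` — calibration tables (standardized coefficients and
  reference Δz values typical of published multi-ethnic elderly norms)
- `vignettes/normative-brain-volumes.Rmd` — the methods notes: model
  assumptions, numerical conventions, what the generator does and does
  not emulate, known limitations
- `tests/testthat/` — unit, property and acceptance suites
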