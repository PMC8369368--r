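---
title: "Normative modeling of regional brain volumes across ethnic groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modeling of regional brain volumes across ethnic groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainnorm)
```

## The problem

A normative model turns a single measurement — here, the FreeSurfer-style
volume of a brain region in cm³ — into a statement about how unusual that
measurement is for a person of a given age, sex, head size, and scanner.
For neurodegenerative disease, the clinically useful quantity is a
z-score: how far below (or, for ventricles, above) the expected volume a
patient sits, in units that account for both population spread and the
uncertainty of the prediction itself.

Most published volumetric norms derive from predominantly Caucasian
cohorts. East Asian and Caucasian elderly differ systematically in
regional volumes even after head-size adjustment, so a norm that omits
ethnicity misreads one group against the other's reference: patients from
the larger-brained group can look "normal" against the other group's
norm precisely in the regions where their disease shows. This package
implements the full workflow for quantifying that effect and for building
norms that correct it.

## The model

For each region $r$, volume (cm³; $\log_{10}$ cm³ for ventricular
regions, whose distribution is strongly right-skewed) is regressed on
demographic and technical covariates by ordinary least squares. Two
variants are fitted:

* **base** (no ethnicity, 11 β terms):
  age, sex, ICV, ICV², ICV³, MFS, manufacturer, sex×age,
  MFS×manufacturer, MFS×ICV, ICV×manufacturer;
* **final** (14 β terms): the base terms plus ethnicity, ethnicity×age
  and ethnicity×sex.

Age enters linearly only: over the restricted range 59–89 years the
age–volume relation is close to linear, and a narrow age window keeps the
model simple and hard to overfit. Intracranial volume (ICV) enters with
quadratic and cubic terms to absorb nonlinear head-size allometry. The
manufacturer factor expands to two dummies (GE vs Siemens, Philips vs
Siemens), so the numeric design has 14 (base) or 17 (final) columns plus
intercept. Dummies are coded first-named-level = 1: Caucasian = 1,
M = 1, 1.5T = 1.

**Numerical choice — ICV centering.** ICV is mean-centered before
powering. Raw cm³ values near 1500 make ICV/ICV²/ICV³ nearly collinear
and the cross-product matrix numerically ill-conditioned; centering fixes
the conditioning without changing the fitted subspace. The centering
constant is stored in every fitted model so that scoring a new subject
reproduces the training columns exactly.

## Single-case z-scores

Scoring a new case uses the standard error of a predicted value for a
new observation (the single-case regression methodology of Crawford and
Garthwaite):

$$ s_{n+1} = s_{V\cdot x}\sqrt{1 + \tfrac1n + \tfrac{1}{n-1}\,
   \mathbf z_0' R^{-1} \mathbf z_0 }, \qquad
   z = \frac{V_0 - \hat V}{s_{n+1}} $$

where $s_{V\cdot x}$ is the residual standard error of the norm
regression, $R^{-1}$ the inverse of the training predictor correlation
matrix, and $\mathbf z_0$ the subject's predictors standardized by the
training means and SDs (sample SD, $n-1$ denominator). Every
non-intercept design column — dummies, polynomial and interaction
columns included — counts as one of the $k$ predictors.

**Numerical choice — standardization convention.** Some presentations of
this formula write the standardized predictor as
$(n-1)(x_{0}-\bar x)/\sum_j (x_j - \bar x)^2$, which is dimensionally
inconsistent with the quadratic form above. We standardize by the sample
SD; under that reading (and only under it) $s_{n+1}$ equals the
classical prediction SE
$s\sqrt{1 + \mathbf x_0'(X'X)^{-1}\mathbf x_0}$ of the
intercept-augmented fit, which the test suite enforces against an
independently implemented hat-matrix oracle at $10^{-8}$.

Degenerate fits ($s_{V\cdot x}\approx 0$, e.g. noiseless synthetic data)
are flagged and refuse to score rather than returning infinite z. A
rank-deficient design is an error naming the dependent columns: silently
dropping columns would desynchronize $R^{-1}$ from the coefficient
vector and corrupt every downstream SE.

Group-level summaries use a one-sample t-test of z against 0 (are
controls centered on the norm?) and Welch's unequal-variance t-test for
between-group Δz contrasts; the variance-equality assumption buys
nothing here and Welch is the safer default. All p-values are two-sided.
Degenerate inputs (all-zero z vectors) return $t = 0, p = 1$ by
convention instead of erroring.

## Variance decomposition

Each model's $R^2$ is split into per-predictor contributions by
averaging the incremental $R^2$ of each predictor group over all $G!$
orders in which the groups can enter the model (the LMG decomposition),
computed exactly through the subset formulation ($2^G$ subset fits with
ordering weights $|S|!\,(G-|S|-1)!/G!$ — trivial at the default
$G = 7$: ethnicity, age, sex, {ICV, ICV², ICV³}, MFS, manufacturer, and
all interactions pooled). Contributions are non-negative and sum to the
full-model $R^2$; the test suite checks the subset computation against
brute-force enumeration of orderings.

**Design choice — no marginality constraint.** When an ordering places
the pooled interaction group before its parent main effects, the
interaction columns enter raw. The plain averaging-over-orderings
definition imposes no hierarchy; imposing one would change the
decomposition and is deliberately not done. The caveat is that the
"interaction" share therefore absorbs some main-effect variance in the
orderings where it enters first.

## Propensity-matched validation groups

The four race×diagnosis validation groups are matched on age, sex and
field strength: a logistic propensity model, then greedy 1:1
nearest-neighbor matching on the logit of the propensity, processing
reference subjects in descending propensity order, without replacement
and with no caliper — the common default of the standard matching tools.
Four-way matching is underdetermined by that description; this package
anchors on the smallest AD group and sequentially matches the other
three groups to it, recording the anchor in the output. Exact-distance
ties are broken by a seeded permutation so matching is reproducible.
Balance is reported as standardized mean differences with the pooled-SD
denominator.

## Diagnostic validation

The classifier is a plain logistic regression on the z-scores of six
regions — bilateral temporal cortex, hippocampus, amygdala — the regions
where AD atrophy concentrates. There are no hyperparameters; 10-fold
cross-validation serves performance estimation only. The ROC is built
from *out-of-fold* predicted probabilities (optimism-free; recorded in
the output metadata), with folds stratified by class so every training
fold contains both classes.

The before/after-ethnicity-adjustment comparison scores the same
subjects under the base and final norms, trains the classifier in each
condition **on one shared fold partition** (the comparison is paired by
subject; pairing the folds too removes partition noise from the AUC
difference), and tests ΔAUC by non-parametric stratified bootstrap:
cases and controls resampled separately with replacement preserving
class counts, $D = \Delta\mathrm{AUC}/\mathrm{SD}_{boot}$, two-sided
normal p-value. Identical score vectors are guarded ($D = 0$, $p = 1$);
fewer than 100 replicates is an error because the SD estimate is
unstable.

**Limitation — near-null degeneracy.** When the two score vectors are
*nearly* identical (e.g. a synthetic world with no ethnic offset, where
the two norms converge to the same function), the bootstrap distribution
of ΔAUC becomes lumpy — the AUC only moves when ranks flip — and the
standard-normal reference for $D$ over-rejects relative to nominal
$\alpha$ even though the same test is well calibrated for genuinely
distinct scoring functions of equal discriminative power. Conclusions
from this test should rest on large $|D|$, not on p-values near the
threshold. The test suite documents this regime honestly rather than
hiding it.

## The synthetic cohort generator

Real multi-ethnic elderly cohorts of the required size cannot be
redistributed, so the package ships a generator that emulates their
statistical structure and makes every stage testable offline:

* **Covariates.** Two ethnic groups; age truncated-normal (mean 73,
  SD 6) on 59–89 (uniform available); per-ethnicity sex ratio (62% / 55%
  female), 3T fraction (81% / 77%), and manufacturer mix (the Korean
  sample is Siemens-only, the Caucasian sample multi-site); ICV normal
  per sex×ethnicity cell (means 1320/1490 and 1360/1540 cm³, SD 110) —
  Caucasians slightly larger ICV, men larger than women. These are
  plausibility values, not estimates.
* **Volumes.** $V = \alpha + \mathbf x'\beta + \varepsilon$ per region
  on the model scale. The shipped coefficients are standardized effect
  sizes typical of published multi-ethnic elderly norms, rescaled to raw
  units via $\beta_j = \beta^{std}_j \, SD(y)/SD(x_j)$ with column SDs
  measured on a large fixed-seed reference draw and
  $SD(y) = RMSE/\sqrt{1-R^2}$; residual SDs are the published-scale
  RMSEs. Effect *directions* and relative magnitudes are therefore
  realistic (Caucasian negative offsets in most gray-matter regions,
  strong positive ICV loading, negative age slopes, ventricular
  enlargement with age); raw-scale fidelity is explicitly not claimed.
  Intercepts anchor predictions at nominal region means.
* **AD atrophy.** AD rows are shifted by a per-region effect (units of
  the residual SD, on the model scale); the default effect vector
  reproduces the canonical after-adjustment AD-vs-CN Δz pattern:
  atrophy concentrated in temporal cortex (≈ −1.2 to −1.4 SD),
  hippocampus (≈ −1.7), amygdala (≈ −1.0 to −1.2), with ventricular
  enlargement (+0.9 to +1.35 on the log scale).

**What the generator does not emulate** — and hence what a green test
does *not* establish: within-subject correlation among region residuals
(regions are drawn independently; real volumes are strongly
co-atrophic), scanner/site batch effects beyond the manufacturer and
field-strength factors, non-Gaussian residuals, longitudinal change, and
an MCI stage. Parameter recovery and z-calibration results transfer to
real data only insofar as the OLS model is correct there.

## Reproducibility

Every stochastic stage takes an explicit seed; the pipeline derives
per-stage streams from one master seed, records all of them plus file
MD5 hashes in a manifest, and two runs from the same config are
byte-identical. All tabular artifacts are CSV with headers; models and
the AUC comparison are JSON; the cohort CSV records its generating seed
in a header comment.
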