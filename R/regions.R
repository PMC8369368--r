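#' Region registry for lobar and subcortical volumes
#'
#' The fixed set of regions the normative pipeline models: whole brain,
#' cortical lobes (left/right), subcortical gray-matter structures, and the
#' ventricular system. Four rows are aggregates (whole brain, cortical GM,
#' subcortical GM, total ventricle) and are flagged as such; selection rules
#' and classifier features operate on constituent regions only. Ventricular
#' volumes are modeled on the log10 scale because their distribution is
#' strongly right-skewed, and carry `log_scale = TRUE`.
#'
#' `mean_volume` is a nominal typical volume for an elderly subject (cm3 on
#' the raw scale; log10(cm3) for log-scale regions). It anchors the
#' intercept of the synthetic ground-truth models and makes no claim of
#' anatomical precision beyond plausibility.
#'
#' @return A data.frame with columns `region` (id), `label` (display name),
#'   `log_scale` (logical), `aggregate` (logical) and `mean_volume`.
#' @export
#' @examples
#' r <- norm_regions()
#' sum(r$log_scale)   # ventricular regions
norm_regions <- function() {
  # nominal means: raw cm3, except log-scale rows which are log10(cm3)
  tab <- rbind(
    c("brain",               "Brain",                FALSE, TRUE,  1000),
    c("cortical_gm",         "Cortical GM",          FALSE, TRUE,  420),
    c("frontal_l",           "Frontal L",            FALSE, FALSE, 74),
    c("frontal_r",           "Frontal R",            FALSE, FALSE, 74),
    c("temporal_l",          "Temporal L",           FALSE, FALSE, 52),
    c("temporal_r",          "Temporal R",           FALSE, FALSE, 52),
    c("parietal_l",          "Parietal L",           FALSE, FALSE, 54),
    c("parietal_r",          "Parietal R",           FALSE, FALSE, 54),
    c("occipital_l",         "Occipital L",          FALSE, FALSE, 22),
    c("occipital_r",         "Occipital R",          FALSE, FALSE, 22),
    c("cingulate_l",         "Cingulate L",          FALSE, FALSE, 12),
    c("cingulate_r",         "Cingulate R",          FALSE, FALSE, 12),
    c("insular_l",           "Insular L",            FALSE, FALSE, 6.5),
    c("insular_r",           "Insular R",            FALSE, FALSE, 6.5),
    c("subcortical_gm",      "Subcortical GM",       FALSE, TRUE,  52),
    c("thalamus_l",          "Thalamus L",           FALSE, FALSE, 6.6),
    c("thalamus_r",          "Thalamus R",           FALSE, FALSE, 6.4),
    c("putamen_l",           "Putamen L",            FALSE, FALSE, 4.6),
    c("putamen_r",           "Putamen R",            FALSE, FALSE, 4.5),
    c("hippocampus_l",       "Hippocampus L",        FALSE, FALSE, 3.4),
    c("hippocampus_r",       "Hippocampus R",        FALSE, FALSE, 3.5),
    c("caudate_l",           "Caudate L",            FALSE, FALSE, 3.2),
    c("caudate_r",           "Caudate R",            FALSE, FALSE, 3.3),
    c("amygdala_l",          "Amygdala L",           FALSE, FALSE, 1.4),
    c("amygdala_r",          "Amygdala R",           FALSE, FALSE, 1.5),
    c("pallidus_l",          "Pallidus L",           FALSE, FALSE, 1.7),
    c("pallidus_r",          "Pallidus R",           FALSE, FALSE, 1.6),
    c("accumbens_l",         "Accumbens L",          FALSE, FALSE, 0.45),
    c("accumbens_r",         "Accumbens R",          FALSE, FALSE, 0.45),
    c("ventral_dc_l",        "Ventral DC L",         FALSE, FALSE, 3.7),
    c("ventral_dc_r",        "Ventral DC R",         FALSE, FALSE, 3.7),
    c("stem",                "Brain stem",           FALSE, FALSE, 19),
    c("corpus_callosum",     "Corpus callosum",      FALSE, FALSE, 2.9),
    c("ventricle",           "Ventricle",            TRUE,  TRUE,  1.45),
    c("lateral_l",           "Lateral ventricle L",  TRUE,  FALSE, 1.05),
    c("lateral_r",           "Lateral ventricle R",  TRUE,  FALSE, 1.00),
    c("inferior_lateral_l",  "Inferior lateral L",   TRUE,  FALSE, -0.10),
    c("inferior_lateral_r",  "Inferior lateral R",   TRUE,  FALSE, -0.05),
    c("third_ventricle",     "3rd ventricle",        TRUE,  FALSE, 0.18),
    c("fourth_ventricle",    "4th ventricle",        TRUE,  FALSE, 0.23)
  )
  data.frame(
    region      = tab[, 1],
    label       = tab[, 2],
    log_scale   = as.logical(tab[, 3]),
    aggregate   = as.logical(tab[, 4]),
    mean_volume = as.numeric(tab[, 5]),
    stringsAsFactors = FALSE
  )
}

#' Default classifier feature regions
#'
#' The six regions used by the diagnostic z-score classifier: bilateral
#' temporal cortex, hippocampus and amygdala — the structures where AD
#' atrophy concentrates and where ethnic offsets in the norms are large.
#'
#' @return Character vector of six region ids.
#' @export
classifier_regions <- function() {
  c("temporal_l", "temporal_r",
    "hippocampus_l", "hippocampus_r",
    "amygdala_l", "amygdala_r")
}
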