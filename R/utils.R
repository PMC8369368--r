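# internal helpers shared across modules

# Derive a stage-specific 31-bit seed from a master seed, so that every
# stochastic stage of a pipeline run has its own reproducible stream.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 13) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(...) {
  stop(structure(class = c("brainnorm_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

abort_data <- function(...) {
  stop(structure(class = c("brainnorm_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_prob_vector <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-12)
    abort_config(what, " must be non-negative and sum to 1 (got sum = ",
                 format(sum(p), digits = 15), ")")
  invisible(p)
}

# column sd with n-1 denominator, matching the standardization convention
# used everywhere in the package (including dummy columns)
col_sds <- function(x) apply(x, 2, stats::sd)

required_covariates <- function() {
  c("subject_id", "ethnicity", "diagnosis", "age", "sex",
    "icv_cm3", "mfs", "manufacturer")
}

check_subjects <- function(subjects) {
  miss <- setdiff(required_covariates(), names(subjects))
  if (length(miss))
    abort_data("subject table is missing columns: ", paste(miss, collapse = ", "))
  invisible(subjects)
}
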