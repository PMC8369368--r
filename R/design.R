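#' Formula specification for the norm regressions
#'
#' Two model variants are supported. The *base* variant predicts volume
#' from age, sex, ICV (linear, quadratic, cubic), field strength,
#' manufacturer, and the interactions sex x age, MFS x manufacturer,
#' MFS x ICV and ICV x manufacturer (11 beta terms). The *final* variant
#' adds ethnicity and the interactions ethnicity x age and ethnicity x sex
#' (14 beta terms). Because the manufacturer factor expands to two dummy
#' columns (GE vs Siemens, Philips vs Siemens), the numeric design has 14
#' columns for the base variant and 17 for the final variant, plus the
#' intercept.
#'
#' Dummy coding follows the first-named-level convention: ethnicity 1 =
#' Caucasian (0 = Korean), sex 1 = M, MFS 1 = 1.5T (0 = 3.0T), and GE /
#' Philips dummies against a Siemens reference.
#'
#' @param variant `"final"` (with ethnicity) or `"base"`.
#' @return An object of class `formula_spec` with elements `variant`,
#'   `terms` (the beta terms of the equation) and `columns` (the expanded
#'   numeric design columns, in fixed equation order).
#' @export
formula_spec <- function(variant = c("final", "base")) {
  variant <- match.arg(variant)
  if (variant == "final") {
    terms <- c("ethnicity", "age", "sex", "icv", "icv2", "icv3", "mfs",
               "manufacturer", "ethnicity:age", "ethnicity:sex", "sex:age",
               "mfs:manufacturer", "mfs:icv", "icv:manufacturer")
    columns <- c("ethnicity", "age", "sex", "icv", "icv2", "icv3", "mfs",
                 "manuf_ge", "manuf_philips", "eth_age", "eth_sex",
                 "sex_age", "mfs_ge", "mfs_philips", "mfs_icv",
                 "icv_ge", "icv_philips")
  } else {
    terms <- c("age", "sex", "icv", "icv2", "icv3", "mfs", "manufacturer",
               "sex:age", "mfs:manufacturer", "mfs:icv", "icv:manufacturer")
    columns <- c("age", "sex", "icv", "icv2", "icv3", "mfs",
                 "manuf_ge", "manuf_philips", "sex_age",
                 "mfs_ge", "mfs_philips", "mfs_icv",
                 "icv_ge", "icv_philips")
  }
  structure(list(variant = variant, terms = terms, columns = columns),
            class = "formula_spec")
}

check_levels <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad))
    abort_data("unknown ", what, " level(s): ", paste(bad, collapse = ", "),
               " (allowed: ", paste(allowed, collapse = ", "), ")")
  invisible(x)
}

#' Build the numeric design matrix for the norm regressions
#'
#' Expands subject covariates into the fixed-order numeric columns of the
#' chosen model variant. ICV is mean-centered before its quadratic and
#' cubic powers are formed (to tame collinearity among the polynomial
#' terms); the centering value is returned so a fitted model can reproduce
#' the exact same columns for new subjects. Interaction columns are
#' elementwise products of their parent columns (with the centered ICV).
#'
#' @param subjects Subject table with columns `ethnicity`, `age`, `sex`,
#'   `icv_cm3`, `mfs`, `manufacturer` (and anything else, ignored).
#' @param spec A [formula_spec()].
#' @param icv_center Centering constant for ICV. `NULL` (default) uses the
#'   mean ICV of `subjects`; pass a stored value when building rows for
#'   scoring against an existing fit.
#' @return An object of class `design_matrix`: list with `x` (numeric
#'   matrix, one row per subject), `columns`, `spec`, `icv_center`.
#' @export
build_design_matrix <- function(subjects, spec = formula_spec(),
                                icv_center = NULL) {
  stopifnot(inherits(spec, "formula_spec"))
  need <- c("ethnicity", "age", "sex", "icv_cm3", "mfs", "manufacturer")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    abort_data("covariates missing from subject table: ",
               paste(miss, collapse = ", "))

  check_levels(subjects$ethnicity, c("Korean", "Caucasian"), "ethnicity")
  check_levels(subjects$sex, c("F", "M"), "sex")
  check_levels(subjects$manufacturer, c("Siemens", "GE", "Philips"),
               "manufacturer")
  mfs_chr <- as.character(subjects$mfs)
  check_levels(mfs_chr, c("1.5", "3"), "MFS")
  if (any(!is.finite(subjects$age)) || any(!is.finite(subjects$icv_cm3)) ||
      any(subjects$icv_cm3 <= 0))
    abort_data("age and ICV must be finite, ICV strictly positive")

  eth <- as.numeric(as.character(subjects$ethnicity) == "Caucasian")
  sex <- as.numeric(as.character(subjects$sex) == "M")
  mfs <- as.numeric(mfs_chr == "1.5")
  ge  <- as.numeric(as.character(subjects$manufacturer) == "GE")
  ph  <- as.numeric(as.character(subjects$manufacturer) == "Philips")
  age <- as.numeric(subjects$age)

  if (is.null(icv_center)) icv_center <- mean(subjects$icv_cm3)
  icv <- as.numeric(subjects$icv_cm3) - icv_center

  cols <- list(
    ethnicity = eth, age = age, sex = sex,
    icv = icv, icv2 = icv^2, icv3 = icv^3,
    mfs = mfs, manuf_ge = ge, manuf_philips = ph,
    eth_age = eth * age, eth_sex = eth * sex, sex_age = sex * age,
    mfs_ge = mfs * ge, mfs_philips = mfs * ph, mfs_icv = mfs * icv,
    icv_ge = icv * ge, icv_philips = icv * ph
  )
  x <- do.call(cbind, cols[spec$columns])
  rownames(x) <- if ("subject_id" %in% names(subjects))
    as.character(subjects$subject_id) else NULL
  structure(list(x = x, columns = spec$columns, spec = spec,
                 icv_center = icv_center),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$x), " subjects x ", ncol(x$x),
      " columns (", x$spec$variant, " variant), ICV centered at ",
      format(x$icv_center, digits = 6), " cm3\n", sep = "")
  invisible(x)
}
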