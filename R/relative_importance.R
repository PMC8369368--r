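#' Default predictor grouping for the variance decomposition
#'
#' Groups the design columns into the conceptual predictors whose
#' importance is reported: ethnicity, age, sex, the three ICV polynomial
#' columns pooled, MFS, the two manufacturer dummies pooled, and all
#' interaction columns pooled into one group. The final variant yields 7
#' groups, the base variant 6; the groups partition the non-intercept
#' columns.
#'
#' @param spec A [formula_spec()].
#' @return Named list of character vectors of design-column names.
#' @export
predictor_grouping <- function(spec = formula_spec()) {
  stopifnot(inherits(spec, "formula_spec"))
  inter <- intersect(c("eth_age", "eth_sex", "sex_age", "mfs_ge",
                       "mfs_philips", "mfs_icv", "icv_ge", "icv_philips"),
                     spec$columns)
  g <- list(age = "age", sex = "sex", icv = c("icv", "icv2", "icv3"),
            mfs = "mfs", manufacturer = c("manuf_ge", "manuf_philips"),
            interaction = inter)
  if (spec$variant == "final") g <- c(list(ethnicity = "ethnicity"), g)
  stopifnot(setequal(unlist(g), spec$columns))
  g
}

# R^2 of an OLS fit of y on the given columns (with intercept)
rsq_subset <- function(x, y, cols, sst) {
  if (length(cols) == 0) return(0)
  xa <- cbind(1, x[, cols, drop = FALSE])
  res <- qr.resid(qr(xa), y)
  1 - sum(res^2) / sst
}

#' Relative importance of predictor groups (orderings-averaged R2)
#'
#' Decomposes the full-model R2 into per-group contributions by averaging
#' each group's incremental R2 over all orderings in which the groups can
#' enter the model (the LMG decomposition, applied to groups of columns).
#' Computed exactly via the subset formulation: the contribution of group
#' `g` is the average of `R2(S + g) - R2(S)` over all subsets `S` of the
#' other groups, weighted by `|S|! (G - |S| - 1)! / G!`. Contributions are
#' non-negative and sum to the full-model R2; the remainder to 100% is
#' reported as unexplained variance.
#'
#' No marginality constraint is imposed: when an ordering places the
#' pooled interaction group before its parent main effects, the
#' interaction columns enter raw. This matches the plain
#' averaging-over-orderings definition (see the methods vignette for the
#' caveat).
#'
#' @param design A [build_design_matrix()] result.
#' @param y Outcome on the fitted scale (log10 already applied for
#'   log-scale regions, as in the model fit).
#' @param grouping Named list from [predictor_grouping()]; at most 10
#'   groups (2^G subset fits).
#' @return List with `contributions` (named, percent of variance),
#'   `unexplained` (percent), `r2_full`.
#' @export
relative_importance <- function(design, y,
                                grouping = predictor_grouping(design$spec)) {
  stopifnot(inherits(design, "design_matrix"))
  G <- length(grouping)
  if (G > 10)
    abort_config(G, " groups exceed the exact-computation guard of 10; ",
                 "sample orderings instead (not implemented)")
  stopifnot(all(unlist(grouping) %in% colnames(design$x)))
  x <- design$x
  sst <- sum((y - mean(y))^2)
  if (sst == 0) abort_data("outcome has zero variance")

  # R^2 of every subset of groups, indexed by bitmask
  r2 <- numeric(2^G)
  for (mask in seq_len(2^G - 1)) {
    inc <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(G) - 1L)) != 0L)
    r2[mask + 1] <- rsq_subset(x, y, unlist(grouping[inc]), sst)
  }

  wts <- factorial(0:(G - 1)) * factorial(G - 1 - 0:(G - 1)) / factorial(G)
  contrib <- numeric(G)
  for (gi in seq_len(G)) {
    bit <- bitwShiftL(1L, gi - 1L)
    for (mask in 0:(2^G - 1)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(G) - 1L)) != 0L)
      contrib[gi] <- contrib[gi] +
        wts[s + 1] * (r2[bitwOr(mask, bit) + 1] - r2[mask + 1])
    }
  }
  names(contrib) <- names(grouping)
  r2_full <- r2[2^G]
  list(contributions = 100 * contrib,
       unexplained = 100 * (1 - r2_full),
       r2_full = r2_full)
}

#' Relative-importance table for many regions
#'
#' @param subjects Training subject table.
#' @param volumes Row-aligned volumes (raw scale; log-scale regions are
#'   transformed internally).
#' @param regions Region ids.
#' @param variant Model variant.
#' @return data.frame: one row per region with per-group percentages and
#'   `unexplained`, summing to 100.
#' @export
relative_importance_table <- function(subjects, volumes, regions = NULL,
                                      variant = "final") {
  reg_tab <- norm_regions()
  regions <- regions %||% intersect(reg_tab$region, names(volumes))
  dm <- build_design_matrix(subjects, formula_spec(variant))
  grouping <- predictor_grouping(dm$spec)
  rows <- lapply(regions, function(reg) {
    lg <- isTRUE(reg_tab$log_scale[match(reg, reg_tab$region)])
    y <- if (lg) log10(volumes[[reg]]) else volumes[[reg]]
    ri <- relative_importance(dm, y, grouping)
    cbind(data.frame(region = reg, stringsAsFactors = FALSE),
          as.data.frame(as.list(ri$contributions)),
          data.frame(unexplained = ri$unexplained))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
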