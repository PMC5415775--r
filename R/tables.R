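#' Dichotomise an IHC score
#'
#' Staining intensity 0 (none) or 1 (weak) is "low"
#' (negative-to-weak); 2 (moderate) or 3 (strong) is "high"
#' (moderate-to-strong). Missing scores stay missing.
#'
#' @param score Integer vector with values in 0..3 or NA.
#' @return Factor with levels `low`, `high`.
#' @export
binarize_score <- function(score) {
  ok <- is.na(score) | score %in% 0:3
  if (!all(ok)) stop("IHC scores must be in 0..3 (or NA)")
  factor(ifelse(is.na(score), NA, ifelse(score >= 2, "high", "low")),
         levels = c("low", "high"))
}

#' Combined FGFR1/FGFR3 staining group
#'
#' Three-level factor from the two dichotomised scores: both low, exactly
#' one high, or both high. Missing either score gives NA.
#'
#' @param fgfr1,fgfr3 Integer scores 0..3 (or NA).
#' @return Factor with levels `both-low`, `one-high`, `both-high`.
#' @export
combined_fgfr_group <- function(fgfr1, fgfr3) {
  h1 <- binarize_score(fgfr1) == "high"
  h3 <- binarize_score(fgfr3) == "high"
  n_high <- as.integer(h1) + as.integer(h3)
  factor(c("both-low", "one-high", "both-high")[n_high + 1L],
         levels = c("both-low", "one-high", "both-high"))
}

#' Derive the standard analysis variables on a cohort table
#'
#' Adds `fgfr1_status` / `fgfr3_status` (low/high), `age_group`
#' (`"<16"` / `">=16"`, pediatric cutoff configurable) and
#' `fgfr_combined` to a cohort table.
#'
#' @param cohort A `cohort_table`.
#' @param pediatric_cutoff Adult age threshold in years (default 16).
#' @return The cohort with the derived columns appended.
#' @export
derive_analysis_vars <- function(cohort, pediatric_cutoff = 16) {
  out <- data.table::as.data.table(cohort)
  out[, fgfr1_status := binarize_score(fgfr1_score)]
  out[, fgfr3_status := binarize_score(fgfr3_score)]
  out[, age_group := factor(ifelse(age < pediatric_cutoff, "<16", ">=16"),
                            levels = c("<16", ">=16"))]
  out[, fgfr_combined := combined_fgfr_group(fgfr1_score, fgfr3_score)]
  out[]
}

#' Cross-tabulate two cohort variables
#'
#' Rows with a missing value in either variable are dropped (pairwise
#' deletion) and counted in the `n_dropped` attribute; empty levels are
#' dropped so the table is at least 2x2.
#'
#' @param cohort A cohort table (after [derive_analysis_vars()] if needed).
#' @param row_var,col_var Column names.
#' @param filter Optional logical vector selecting rows first.
#' @return Integer matrix with dimnames; attributes `n_used`, `n_dropped`.
#' @export
crosstab <- function(cohort, row_var, col_var, filter = NULL) {
  dt <- data.table::as.data.table(cohort)
  if (!is.null(filter)) dt <- dt[filter]
  rv <- dt[[row_var]]; cv <- dt[[col_var]]
  if (is.null(rv) || is.null(cv)) stop("unknown variable name")
  keep <- !is.na(rv) & !is.na(cv)
  tab <- table(droplevels(as.factor(rv[keep])), droplevels(as.factor(cv[keep])))
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table degenerate after dropping empty levels")
  m <- unclass(as.matrix(tab))
  attr(m, "n_used") <- sum(keep)
  attr(m, "n_dropped") <- sum(!keep)
  names(dimnames(m)) <- c(row_var, col_var)
  m
}

#' Published ependymoma IHC cross-tabulations
#'
#' The low/high staining counts of the motivating 108-sample ependymoma
#' cohort, cross-tabulated against tumour location, grade and patient age
#' group, as printed in the study this package re-implements. Bundled so
#' the association analyses can be reproduced without patient-level data.
#'
#' Each element is an r x 2 matrix (rows: variable levels, columns:
#' low/high staining).
#'
#' @return Named list of matrices: `fgfr1_location`, `fgfr3_location`,
#'   `fgfr1_grade`, `fgfr3_grade`, `fgfr1_age`, `fgfr3_age`.
#' @export
ependymoma_ihc_counts <- function() {
  mk <- function(vals, rows) {
    m <- matrix(vals, ncol = 2, byrow = TRUE,
                dimnames = list(rows, c("low", "high")))
    storage.mode(m) <- "integer"
    m
  }
  list(
    fgfr1_location = mk(c(37, 6, 21, 4, 16, 20), c("spinal", "cerebellar", "cerebral")),
    fgfr3_location = mk(c(41, 2, 23, 5, 20, 15), c("spinal", "cerebellar", "cerebral")),
    fgfr1_grade = mk(c(16, 2, 50, 15, 10, 13), c("I", "II", "III")),
    fgfr3_grade = mk(c(18, 0, 54, 14, 14, 8), c("I", "II", "III")),
    fgfr1_age = mk(c(22, 12, 50, 18), c("<16", ">=16")),
    fgfr3_age = mk(c(23, 12, 61, 10), c("<16", ">=16")))
}

#' Association report over variable pairs
#'
#' Runs the r x c Fisher test for each requested variable pair and returns
#' a tidy report (one row per pair) with the method, p-value and, for
#' Monte-Carlo runs, the replicate count, seed and standard error.
#'
#' @param cohort A cohort table (derived variables are added if missing).
#' @param pairs Character vector like `"fgfr3_status:location"`.
#' @param method,replicates,seed Passed to [fisher_exact_rxc()].
#' @return data.table: `row_var`, `col_var`, `method`, `p`, `replicates`,
#'   `mc_se`, `n_used`.
#' @export
associate_pairs <- function(cohort, pairs, method = "monte-carlo",
                            replicates = 1e6, seed = 1L) {
  dt <- data.table::as.data.table(cohort)
  if (!"fgfr3_status" %in% names(dt)) dt <- derive_analysis_vars(dt)
  rows <- lapply(seq_along(pairs), function(i) {
    vars <- strsplit(pairs[i], ":", fixed = TRUE)[[1]]
    tab <- crosstab(dt, vars[1], vars[2])
    res <- fisher_exact_rxc(tab, method = method, replicates = replicates,
                            seed = seed + i)
    data.table::data.table(
      row_var = vars[1], col_var = vars[2], method = res$method,
      p = res$p.value,
      replicates = if (is.null(res$replicates)) NA_real_ else res$replicates,
      mc_se = if (is.null(res$mc_se)) NA_real_ else res$mc_se,
      n_used = attr(tab, "n_used"))
  })
  data.table::rbindlist(rows)
}
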