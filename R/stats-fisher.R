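#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and sums hypergeometric point probabilities
#' over all tables at most as probable as the observed one (the
#' "probability-based" two-sided convention used by standard statistical
#' software). A relative tolerance of 1e-7 guards ties in the point
#' probabilities.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List of class `assoc_test`: `p.value`, `method`, `table`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0)) stop("negative cell counts")
  storage.mode(tab) <- "double"
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(x_obs, r1, r2, c1)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  structure(list(p.value = min(p, 1), method = "fisher-2x2-exact",
                 table = tab), class = "assoc_test")
}

# log point probability of an r x c table under fixed margins
table_log_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

# enumerate all tables with the given margins, calling f(cells) per table;
# aborts when more than `limit` tables are generated
enumerate_margin_tables <- function(row_sums, col_sums, f, limit = 1e7) {
  r <- length(row_sums); cc <- length(col_sums)
  count <- 0L
  cells <- matrix(0, r, cc)
  rec_row <- function(i, rem_cols) {
    if (i == r) {
      # last row forced
      if (any(rem_cols < 0)) return()
      cells[r, ] <<- rem_cols
      count <<- count + 1L
      if (count > limit) stop("fixed-margin table space exceeds enumeration limit; use monte-carlo")
      f(cells)
      return()
    }
    fill_cell(i, 1L, row_sums[i], rem_cols)
  }
  fill_cell <- function(i, j, rem_row, rem_cols) {
    if (j == cc) {
      if (rem_row > rem_cols[cc]) return()
      cells[i, cc] <<- rem_row
      rec_row(i + 1L, rem_cols - cells[i, ])
      return()
    }
    for (v in 0:min(rem_row, rem_cols[j])) {
      cells[i, j] <<- v
      fill_cell(i, j + 1L, rem_row - v, rem_cols)
    }
  }
  rec_row(1L, col_sums)
  count
}

#' Fisher's exact test for r x c tables (enumeration or Monte Carlo)
#'
#' `method = "enumerate"` walks every table with the observed margins and
#' sums the probabilities of those at most as probable as the observed
#' table (exact two-sided p). `method = "monte-carlo"` samples tables from
#' the fixed-margin (permutation) distribution via Patefield's algorithm
#' ([stats::r2dtable]) and reports the add-one estimator
#' `(1 + #{prob <= observed}) / (replicates + 1)` with its standard error.
#' The published analyses used 2.5e7 replicates; that is the default.
#'
#' @param table r x c matrix of non-negative integer counts.
#' @param method `"enumerate"` or `"monte-carlo"`.
#' @param replicates Monte-Carlo replicate count.
#' @param seed Seed for the Monte-Carlo draw (required for reproducibility).
#' @param enumeration_limit Refuse to enumerate beyond this many tables.
#' @return List of class `assoc_test`: `p.value`, `method`, `table`, and
#'   for Monte-Carlo runs `replicates`, `seed`, `mc_se`.
#' @export
fisher_exact_rxc <- function(table, method = c("enumerate", "monte-carlo"),
                             replicates = 2.5e7, seed = 1L,
                             enumeration_limit = 1e7) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("negative cell counts")
  storage.mode(tab) <- "double"
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("empty row or column margin")
  logp_obs <- table_log_prob(tab)
  tol <- 1e-7

  if (method == "enumerate") {
    acc <- 0
    enumerate_margin_tables(rs, cs, function(cells) {
      lp <- table_log_prob(cells)
      if (lp <= logp_obs + tol) acc <<- acc + exp(lp)
    }, limit = enumeration_limit)
    return(structure(list(p.value = min(acc, 1), method = "exact-enumeration",
                          table = tab), class = "assoc_test"))
  }

  set.seed(seed)
  # compare on the sum of cell log-factorials: prob <= observed prob
  # exactly when sum(lfactorial(cells)) >= sum(lfactorial(observed))
  lf_obs <- sum(lfactorial(tab))
  hits <- 0
  remaining <- replicates
  chunk <- 1e5L
  while (remaining > 0) {
    m <- min(chunk, remaining)
    draws <- stats::r2dtable(m, rs, cs)
    lf <- colSums(matrix(lfactorial(unlist(draws)), nrow = length(tab)))
    hits <- hits + sum(lf >= lf_obs - tol)
    remaining <- remaining - m
  }
  p <- (1 + hits) / (replicates + 1)
  structure(list(p.value = p, method = "monte-carlo",
                 replicates = replicates, seed = seed,
                 mc_se = sqrt(p * (1 - p) / replicates),
                 table = tab), class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s: p = %.6g", x$method, x$p.value))
  if (!is.null(x$mc_se))
    cat(sprintf(" (MC se %.2g, %g replicates, seed %d)",
                x$mc_se, x$replicates, x$seed))
  cat("\n")
  invisible(x)
}
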