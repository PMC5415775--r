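# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# brute-force ungapped placement: scan every position on both strands with
# Biostrings mismatch counting; returns all best placements within budget
brute_force_place <- function(seq, reference, max_mismatch = 5L) {
  L <- nchar(seq)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    pat <- Biostrings::DNAString(s)
    for (chrom in names(reference)) {
      subj <- reference[[chrom]]
      n <- length(subj) - L + 1L
      if (n < 1L) next
      ed <- Biostrings::neditStartingAt(pat, subj, starting.at = seq_len(n))
      w <- which(ed <= max_mismatch)
      for (p in w)
        hits[[length(hits) + 1L]] <- list(chrom = chrom, pos = p,
                                          strand = strand, nm = ed[p])
    }
  }
  if (!length(hits)) return(NULL)
  nm <- vapply(hits, `[[`, integer(1), "nm")
  hits[nm == min(nm)]
}

# full enumeration two-sided Fisher p for a 2x2 table using choose() only
fisher_2x2_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, c1 - tab[1, 1]) / choose(n, c1)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# brute-force two-group log-rank via explicit per-event-time 2x2 tables
logrank_oracle <- function(times, events, group) {
  events <- as.logical(events)
  g1 <- group == sort(unique(group))[1]
  O <- E <- V <- 0
  for (t in sort(unique(times[events]))) {
    n <- sum(times >= t); n1 <- sum(times >= t & g1)
    d <- sum(times == t & events); d1 <- sum(times == t & events & g1)
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n - n1) / n * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# written-out Breslow partial log-likelihood for one covariate (no ties)
cox_loglik_1d <- function(beta, times, events, x) {
  ll <- 0
  events <- as.logical(events)
  for (t in times[events]) {
    rs <- times >= t
    i <- which(times == t & events)
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[rs])))
  }
  ll
}
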