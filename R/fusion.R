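#' Collect the unaligned read pool
#'
#' Rearrangement evidence lives in the reads the contiguous aligner could
#' not place (junction-spanning reads have no single reference origin).
#'
#' @param alignments From [align_reads()] or [import_sam()].
#' @return Character vector of unaligned read ids, in stable input order.
#' @export
collect_unaligned <- function(alignments) {
  alignments$read_id[alignments$status == "unaligned"]
}

#' Split reads into two 30-bp anchors
#'
#' Each read contributes its first and last `anchor_length` bases. Reads
#' shorter than twice the anchor length cannot be split and are skipped;
#' the skip count is recorded as an attribute.
#'
#' @param reads data.table with `read_id`, `seq` (typically the unaligned
#'   pool).
#' @param anchor_length Anchor size in bp (default 30).
#' @return data.table of class `anchor_pairs`: `read_id`, `anchorA`,
#'   `anchorB`; attribute `skipped` counts too-short reads.
#' @export
split_anchors <- function(reads, anchor_length = 30L) {
  rd <- data.table::as.data.table(reads)
  anchor_length <- as.integer(anchor_length)
  len <- nchar(rd$seq)
  ok <- len >= 2L * anchor_length
  out <- data.table::data.table(
    read_id = rd$read_id[ok],
    anchorA = substr(rd$seq[ok], 1L, anchor_length),
    anchorB = substring(rd$seq[ok], len[ok] - anchor_length + 1L, len[ok]))
  data.table::setattr(out, "skipped", sum(!ok))
  data.table::setattr(out, "anchor_length", anchor_length)
  data.table::setattr(out, "class", c("anchor_pairs", class(out)))
  out[]
}

# place one anchor: exact unique match on either strand, with a <=1-mismatch
# fallback when no exact hit exists; ambiguous anchors are unplaced
place_anchor <- function(anchor, rc, ki) {
  hits_f <- mget(anchor, envir = ki$index, ifnotfound = list(NULL))[[1]]
  hits_r <- mget(rc, envir = ki$index, ifnotfound = list(NULL))[[1]]
  n <- length(hits_f) + length(hits_r)
  if (n == 1L) {
    if (length(hits_f)) {
      ci <- floor(hits_f / 1e9)
      return(list(chrom = ki$chroms[ci], pos = as.integer(hits_f - ci * 1e9), strand = "+"))
    }
    ci <- floor(hits_r / 1e9)
    return(list(chrom = ki$chroms[ci], pos = as.integer(hits_r - ci * 1e9), strand = "-"))
  }
  if (n > 1L) return(NULL)                  # multi-mapping: unplaced
  # <=1 mismatch fallback
  cand <- list()
  for (strand in c("+", "-")) {
    a <- if (strand == "+") anchor else rc
    for (p in seq_len(nchar(a))) {
      for (b in setdiff(BASES, substr(a, p, p))) {
        v <- a
        substr(v, p, p) <- b
        h <- mget(v, envir = ki$index, ifnotfound = list(NULL))[[1]]
        for (enc in h) cand[[length(cand) + 1L]] <- c(enc, strand == "-")
      }
    }
  }
  if (length(cand) != 1L) return(NULL)
  enc <- cand[[1]][1]; minus <- cand[[1]][2] == 1
  ci <- floor(enc / 1e9)
  list(chrom = ki$chroms[ci], pos = as.integer(enc - ci * 1e9),
       strand = if (minus) "-" else "+")
}

#' Align anchors to the reference
#'
#' Exact 30-mer lookup on both strands with a one-mismatch fallback;
#' anchors matching more than one locus are left unplaced (ambiguity rule).
#'
#' @param anchor_pairs From [split_anchors()].
#' @param reference `DNAStringSet`.
#' @param index Optional prebuilt [ref_kmer_index()] with `k` equal to the
#'   anchor length.
#' @return The input with placement columns `chromA`, `posA`, `strandA`,
#'   `chromB`, `posB`, `strandB` (NA when unplaced).
#' @export
align_anchors <- function(anchor_pairs, reference, index = NULL) {
  alen <- attr(anchor_pairs, "anchor_length")
  ki <- if (is.null(index)) ref_kmer_index(reference, k = alen) else index
  if (ki$k != alen) stop("index k does not match anchor length")
  out <- data.table::copy(anchor_pairs)

  place_col <- function(anchors) {
    ua <- unique(anchors)
    urc <- revcomp_chr(ua)
    pl <- mapply(place_anchor, ua, urc, MoreArgs = list(ki = ki),
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
    pl[match(anchors, ua)]
  }
  for (side in c("A", "B")) {
    pl <- place_col(out[[paste0("anchor", side)]])
    hit <- !vapply(pl, is.null, logical(1))
    out[, (paste0("chrom", side)) := ifelse(hit, vapply(pl, function(x) if (is.null(x)) NA_character_ else x$chrom, character(1)), NA_character_)]
    out[, (paste0("pos", side)) := ifelse(hit, vapply(pl, function(x) if (is.null(x)) NA_integer_ else x$pos, integer(1)), NA_integer_)]
    out[, (paste0("strand", side)) := ifelse(hit, vapply(pl, function(x) if (is.null(x)) NA_character_ else x$strand, character(1)), NA_character_)]
  }
  out[]
}

#' Classify anchor pairs as discordant
#'
#' A pair is discordant when its two anchors cannot come from one
#' contiguous genomic fragment: different chromosomes, an implied span
#' larger than `max_span` (or negative), or inconsistent orientation.
#' Pairs with an unplaced anchor are not classifiable and are excluded
#' (their count is kept as an attribute).
#'
#' @param anchor_pairs Placed pairs from [align_anchors()].
#' @param max_span Maximum implied fragment span for a concordant pair.
#' @return The classifiable subset with a logical `discordant` column;
#'   attribute `unplaced` counts excluded pairs.
#' @export
classify_discordant <- function(anchor_pairs, max_span = 10000L) {
  ap <- data.table::as.data.table(anchor_pairs)
  placed <- !is.na(ap$posA) & !is.na(ap$posB)
  out <- ap[placed]
  alen <- attr(anchor_pairs, "anchor_length")
  if (is.null(alen)) alen <- 30L
  span <- ifelse(out$strandA == "+",
                 out$posB + alen - out$posA,   # forward read: B right of A
                 out$posA + alen - out$posB)
  out[, discordant := chromA != chromB | strandA != strandB |
        span <= 0L | span > max_span]
  data.table::setattr(out, "unplaced", sum(!placed))
  data.table::setattr(out, "anchor_length", alen)
  out[]
}

#' Group discordant pairs into rearrangement candidates
#'
#' Single-linkage clustering of discordant pairs that share the chromosome
#' pair and orientation and whose A-side and B-side positions each lie
#' within `window` of another member. A candidate is flagged when it is
#' supported by at least `min_support` distinct reads. Breakpoints are
#' reported as the median innermost anchor coordinate on each side.
#'
#' @param pairs Classified pairs from [classify_discordant()].
#' @param window Clustering window in bp.
#' @param min_support Distinct supporting reads needed to flag a candidate.
#' @param panel Optional `panel_design` used to attach gene labels.
#' @return data.table of class `rearrangement_candidates`: `chromA`,
#'   `breakpointA`, `strandA`, `chromB`, `breakpointB`, `strandB`,
#'   `n_support`, `flagged`, `geneA`, `geneB`, `read_ids` (list column).
#' @export
group_candidates <- function(pairs, window = 500L, min_support = 8L,
                             panel = NULL) {
  dp <- data.table::as.data.table(pairs)[discordant == TRUE]
  alen <- attr(pairs, "anchor_length")
  if (is.null(alen)) alen <- 30L
  empty <- data.table::data.table(
    chromA = character(), breakpointA = integer(), strandA = character(),
    chromB = character(), breakpointB = integer(), strandB = character(),
    n_support = integer(), flagged = logical(),
    geneA = character(), geneB = character(), read_ids = list())
  if (!nrow(dp)) {
    data.table::setattr(empty, "class", c("rearrangement_candidates", class(empty)))
    return(empty[])
  }

  dp[, grp_key := paste(chromA, chromB, strandA, strandB, sep = "|")]
  res <- list()
  for (gk in unique(dp$grp_key)) {
    sub <- dp[grp_key == gk]
    data.table::setorder(sub, posA, posB)
    n <- nrow(sub)
    # single-linkage: union-find over pairs close on both sides
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      if (abs(sub$posA[i] - sub$posA[j]) <= window &&
          abs(sub$posB[i] - sub$posB[j]) <= window) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cid in unique(comp)) {
      m <- sub[comp == cid]
      # innermost base of each anchor: A extends to its right end on a
      # forward read, B starts at its left end
      bpA <- if (m$strandA[1] == "+") stats::median(m$posA + alen - 1L) else stats::median(m$posA)
      bpB <- if (m$strandB[1] == "+") stats::median(m$posB) else stats::median(m$posB + alen - 1L)
      ids <- unique(m$read_id)
      res[[length(res) + 1L]] <- data.table::data.table(
        chromA = m$chromA[1], breakpointA = as.integer(round(bpA)), strandA = m$strandA[1],
        chromB = m$chromB[1], breakpointB = as.integer(round(bpB)), strandB = m$strandB[1],
        n_support = length(ids), flagged = length(ids) >= min_support,
        geneA = NA_character_, geneB = NA_character_,
        read_ids = list(sort(ids)))
    }
  }
  out <- data.table::rbindlist(res)
  if (!is.null(panel)) {
    p <- data.table::as.data.table(panel)
    label <- function(ch, po) {
      w <- which(p$chrom == ch & p$start <= po & p$end >= po & !p$is_control)
      if (length(w)) p$gene[w[1]] else NA_character_
    }
    out[, geneA := mapply(label, chromA, breakpointA)]
    out[, geneB := mapply(label, chromB, breakpointB)]
  }
  data.table::setorder(out, chromA, breakpointA, chromB, breakpointB)
  data.table::setattr(out, "class", c("rearrangement_candidates", class(out)))
  out[]
}

#' One-call rearrangement detection
#'
#' Runs the full chain: unaligned pool -> anchor split -> anchor alignment
#' -> discordance classification -> clustering.
#'
#' @param alignments,reads,reference As in the stagewise functions.
#' @param panel Optional panel for gene labels.
#' @param anchor_length,max_span,window,min_support Stage parameters.
#' @export
detect_rearrangements <- function(alignments, reads, reference, panel = NULL,
                                  anchor_length = 30L, max_span = 10000L,
                                  window = 500L, min_support = 8L) {
  rd <- if (inherits(reads, "simulated_sample")) reads$reads else data.table::as.data.table(reads)
  pool <- rd[rd$read_id %in% collect_unaligned(alignments), ]
  ap <- split_anchors(pool, anchor_length)
  ap <- align_anchors(ap, reference)
  cl <- classify_discordant(ap, max_span)
  group_candidates(cl, window, min_support, panel)
}

#' Write rearrangement candidates as BEDPE (+ JSON evidence)
#'
#' BEDPE intervals are 0-based half-open single-base breakpoints; the name
#' field is `geneA-geneB` (or `.`), the score the supporting-read count.
#'
#' @param candidates From [group_candidates()].
#' @param path BEDPE output path.
#' @param evidence_path Optional JSON path listing member reads.
#' @param flagged_only Write only flagged candidates (default TRUE).
#' @export
write_bedpe <- function(candidates, path, evidence_path = NULL,
                        flagged_only = TRUE) {
  cc <- data.table::as.data.table(candidates)
  if (flagged_only) cc <- cc[flagged == TRUE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s",
                   cc$chromA, cc$breakpointA - 1L, cc$breakpointA,
                   cc$chromB, cc$breakpointB - 1L, cc$breakpointB,
                   ifelse(is.na(cc$geneA) & is.na(cc$geneB), ".",
                          paste0(cc$geneA, "-", cc$geneB)),
                   cc$n_support, cc$strandA, cc$strandB)
  writeLines(lines, path)
  if (!is.null(evidence_path)) {
    jsonlite::write_json(
      lapply(seq_len(nrow(cc)), function(i) list(
        chromA = cc$chromA[i], breakpointA = cc$breakpointA[i],
        chromB = cc$chromB[i], breakpointB = cc$breakpointB[i],
        n_support = cc$n_support[i], flagged = cc$flagged[i],
        reads = cc$read_ids[[i]])),
      evidence_path, auto_unbox = TRUE)
  }
  invisible(path)
}
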