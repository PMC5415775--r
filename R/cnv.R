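#' Count aligned reads per amplicon
#'
#' A read increments the amplicon whose interval contains its leftmost
#' aligned position; duplicate-flagged reads are excluded. Reads matching
#' no amplicon are counted separately (attribute `unassigned`).
#'
#' @param alignments From [align_reads()] or [import_sam()].
#' @param panel `panel_design`.
#' @return data.table of class `amplicon_counts`: `amplicon_id`, `chrom`,
#'   `start`, `end`, `gene`, `is_control`, `count`; attribute `unassigned`.
#' @export
count_amplicons <- function(alignments, panel) {
  al <- data.table::as.data.table(alignments)
  al <- al[status == "aligned" & duplicate == FALSE]
  p <- data.table::as.data.table(panel)
  counts <- integer(nrow(p))
  assigned <- 0L
  for (cc in unique(p$chrom)) {
    pos <- al$pos[al$chrom == cc]
    if (!length(pos)) next
    rows <- which(p$chrom == cc)
    ord <- rows[order(p$start[rows])]
    starts <- p$start[ord]; ends <- p$end[ord]
    # overlapping tiles can both contain a position; assign each read to
    # exactly one amplicon — the latest-starting one containing it
    cand <- findInterval(pos, starts)
    direct <- cand >= 1L & pos <= ends[pmax(cand, 1L)]
    if (any(direct)) {
      tab <- tabulate(cand[direct], nbins = length(ord))
      counts[ord] <- counts[ord] + tab
      assigned <- assigned + sum(direct)
    }
    for (i in which(!direct)) {       # rare: walk back through overlaps
      j <- cand[i]
      while (j >= 1L && pos[i] > ends[j]) j <- j - 1L
      if (j >= 1L && pos[i] >= starts[j]) {
        counts[ord[j]] <- counts[ord[j]] + 1L
        assigned <- assigned + 1L
      }
    }
  }
  out <- data.table::data.table(p[, c("amplicon_id", "chrom", "start", "end",
                                      "gene", "is_control")], count = counts)
  data.table::setattr(out, "unassigned", nrow(al) - assigned)
  data.table::setattr(out, "class", c("amplicon_counts", class(out)))
  out[]
}

#' Between-sample coverage correction factor
#'
#' The control amplicons sit in copy-number-quiet regions, so their counts
#' measure a sample's overall coverage. The correction factor is the median
#' control-amplicon count; corrected counts are raw counts divided by it.
#'
#' @param counts An `amplicon_counts` table.
#' @param stat `"median"` (default) or `"mean"` over control amplicons.
#' @return The scaling factor (numeric scalar).
#' @export
coverage_correction <- function(counts, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  ctrl <- counts$count[counts$is_control]
  if (!length(ctrl)) stop("panel has no control amplicons")
  if (all(ctrl == 0)) stop("all control amplicons have zero counts")
  if (stat == "median") stats::median(ctrl) else mean(ctrl)
}

#' Copy-number log ratios against a baseline
#'
#' Corrects both samples by their control-amplicon factors, then computes
#' per-amplicon `log2((tumor_corr + c) / (baseline_corr + c))` with the
#' pseudocount `c` applied on the corrected scale (where neutral coverage
#' is 1), keeping the ratios exactly invariant to a global rescaling of
#' either sample's counts while still stabilising zero counts. Gene
#' summaries are the median log ratio over the gene's amplicons, called
#' `loss` / `neutral` / `gain` against the configured thresholds. Control
#' amplicons contribute ratios but never gene calls.
#'
#' @param tumor,baseline `amplicon_counts` on the same panel (baseline is
#'   typically blood-derived DNA from healthy individuals, or a pool).
#' @param pseudocount Added (on the corrected scale, neutral = 1) to
#'   numerator and denominator to stabilise zero counts; the default 1e-3
#'   corresponds to half a read at a typical 500x amplicon depth.
#' @param loss,gain Log2-ratio call thresholds.
#' @param stat Control-amplicon statistic passed to [coverage_correction()].
#' @return List of class `cnv_profile`: `amplicons` (per-amplicon table
#'   with `raw`, `corrected`, `log2_ratio`), `genes` (per-gene `median_log2`
#'   and `call`), `factor_tumor`, `factor_baseline`.
#' @export
log_ratios <- function(tumor, baseline, pseudocount = 1e-3,
                       loss = -0.5, gain = 0.5, stat = "median") {
  if (!identical(tumor$amplicon_id, baseline$amplicon_id))
    stop("tumor and baseline counts cover different amplicon sets")
  ft <- coverage_correction(tumor, stat)
  fb <- coverage_correction(baseline, stat)
  t_corr <- tumor$count / ft
  b_corr <- baseline$count / fb
  r <- log2((t_corr + pseudocount) / (b_corr + pseudocount))
  amp <- data.table::data.table(
    amplicon_id = tumor$amplicon_id, chrom = tumor$chrom, gene = tumor$gene,
    is_control = tumor$is_control, raw = tumor$count, corrected = t_corr,
    log2_ratio = r)
  genes <- amp[is_control == FALSE & !is.na(gene),
               list(median_log2 = stats::median(log2_ratio),
                    n_amplicons = .N), by = "gene"]
  genes[, call := ifelse(median_log2 <= loss, "loss",
                         ifelse(median_log2 >= gain, "gain", "neutral"))]
  structure(list(amplicons = amp[], genes = genes[],
                 factor_tumor = ft, factor_baseline = fb,
                 thresholds = c(loss = loss, gain = gain)),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("cnv_profile:", nrow(x$amplicons), "amplicons,",
      nrow(x$genes), "genes\n")
  print(x$genes)
  invisible(x)
}

#' Write a copy-number profile as TSV
#'
#' Two files: per-amplicon (`amplicon_id`, `gene`, `raw`, `corrected`,
#' `log2_ratio`) and per-gene with the call column.
#'
#' @param profile A `cnv_profile`.
#' @param amplicon_path,gene_path Output paths (either may be NULL).
#' @export
write_cnv_tsv <- function(profile, amplicon_path = NULL, gene_path = NULL) {
  if (!is.null(amplicon_path))
    data.table::fwrite(profile$amplicons[, c("amplicon_id", "gene", "raw",
                                             "corrected", "log2_ratio")],
                       amplicon_path, sep = "\t")
  if (!is.null(gene_path))
    data.table::fwrite(profile$genes, gene_path, sep = "\t")
  invisible(NULL)
}
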