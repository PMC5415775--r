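#' Build per-site pileups over the panel footprint
#'
#' Tallies base counts at every reference position covered by a panel
#' amplicon, from the aligned reads. Minus-strand placements contribute the
#' reverse complement of the stored read (i.e. the reference-forward
#' bases). Duplicate-flagged reads are excluded when `dedupe` is on.
#'
#' @param alignments From [align_reads()] or [import_sam()].
#' @param reads Read table (`read_id`, `seq`); ignored if `alignments`
#'   carries its own `seq` column (SAM import).
#' @param reference `DNAStringSet`.
#' @param panel `panel_design` defining the sites to report.
#' @param dedupe Drop duplicate-flagged reads (default TRUE).
#' @return data.table of class `pileup`: `chrom`, `pos`, `ref`, `A`, `C`,
#'   `G`, `T`, `depth`.
#' @export
build_pileup <- function(alignments, reads = NULL, reference, panel, dedupe = TRUE) {
  al <- data.table::as.data.table(alignments)
  if (!"seq" %in% names(al)) {
    rd <- if (inherits(reads, "simulated_sample")) reads$reads else data.table::as.data.table(reads)
    if (is.null(rd)) stop("`reads` required when alignments carry no sequences")
    al[, seq := rd$seq[match(al$read_id, rd$read_id)]]
    if (anyNA(al$seq[al$status == "aligned"])) stop("alignments refer to unknown reads")
  }
  al <- al[status == "aligned"]
  if (dedupe) al <- al[duplicate == FALSE]

  chrom_seq <- stats::setNames(as.character(reference), names(reference))
  chrom_len <- nchar(chrom_seq)

  # panel site list (union of amplicon intervals per chromosome)
  sites <- unique(data.table::as.data.table(panel)[
    , list(pos = unlist(Map(seq.int, start, end))), by = "chrom"])

  base_code <- integer(256)
  base_code[utf8ToInt("A") + 1L] <- 1L
  base_code[utf8ToInt("C") + 1L] <- 2L
  base_code[utf8ToInt("G") + 1L] <- 3L
  base_code[utf8ToInt("T") + 1L] <- 4L

  count_mats <- list()
  for (cc in unique(sites$chrom)) {
    sub <- al[chrom == cc]
    L <- chrom_len[[cc]]
    mat <- matrix(0L, nrow = 4L, ncol = L)
    if (nrow(sub)) {
      eff <- sub$seq
      minus <- sub$strand == "-"
      if (any(minus)) eff[minus] <- revcomp_chr(eff[minus])
      lens <- nchar(eff)
      pos <- sequence(lens, from = sub$pos)          # genomic position per base
      codes <- base_code[as.integer(charToRaw(paste(eff, collapse = ""))) + 1L]
      keep <- codes > 0L & pos >= 1L & pos <= L
      idx <- (pos[keep] - 1L) * 4L + codes[keep]
      mat[] <- tabulate(idx, nbins = 4L * L)
    }
    count_mats[[cc]] <- mat
  }

  sites[, ref := substring(chrom_seq[chrom], pos, pos)]
  for (b in seq_along(BASES))
    sites[, (BASES[b]) := count_mats[[.BY$chrom]][b, pos], by = "chrom"]
  sites[, depth := A + C + G + T]
  data.table::setorder(sites, chrom, pos)
  data.table::setcolorder(sites, c("chrom", "pos", "ref", "A", "C", "G", "T", "depth"))
  data.table::setattr(sites, "class", c("pileup", class(sites)))
  sites[]
}

#' Estimate the background error model from control bloods
#'
#' For every panel site and alternate base, the background rate is the
#' arithmetic mean of the per-sample alternate allele fractions across the
#' control blood samples; zero-depth sites are excluded from a sample's
#' contribution. The mean is then floored at `floor` so that sites that
#' happen to be error-free in the controls do not make the downstream
#' ratio rule vacuous.
#'
#' @param control_pileups List of `pileup` objects, one per control sample.
#' @param floor Global floor epsilon on the background rate.
#' @return data.table of class `background_model`: `chrom`, `pos`, `ref`,
#'   `alt`, `b`, `n_samples`; attribute `floor`.
#' @export
estimate_background <- function(control_pileups, floor = 1e-4) {
  if (!length(control_pileups)) stop("at least one control sample is required")
  base <- control_pileups[[1]][, c("chrom", "pos", "ref")]
  long <- data.table::rbindlist(lapply(seq_along(control_pileups), function(i) {
    p <- control_pileups[[i]]
    if (!identical(p$chrom, base$chrom) || !identical(p$pos, base$pos))
      stop("control pileups cover different site sets")
    data.table::rbindlist(lapply(BASES, function(b) {
      data.table::data.table(chrom = p$chrom, pos = p$pos, ref = p$ref,
                             alt = b, frac = p[[b]] / p$depth,
                             has_depth = p$depth > 0)
    }))
  }))
  long <- long[alt != ref]
  bg <- long[, list(
    b = if (any(has_depth)) mean(frac[has_depth]) else NA_real_,
    n_samples = sum(has_depth)), by = c("chrom", "pos", "ref", "alt")]
  bg[, b := pmax(b, floor)]
  bg[is.na(b), b := floor]
  data.table::setorder(bg, chrom, pos, alt)
  data.table::setattr(bg, "floor", floor)
  data.table::setattr(bg, "class", c("background_model", class(bg)))
  bg[]
}

#' Call point mutations with the background-calibrated filter
#'
#' One candidate per (site, non-reference base with at least one read).
#' A call PASSes exactly when its allele fraction is at least `min_af`,
#' its alternate read count at least `min_alt`, and its allele fraction at
#' least `bg_factor` times the site's background error rate. All three
#' thresholds are inclusive and configurable; the defaults (0.10, 5, 20)
#' are the published filter.
#'
#' @param pileup A `pileup` (tumour sample).
#' @param background A `background_model` covering the pileup's sites.
#' @param min_af Minimum alternate allele fraction.
#' @param min_alt Minimum alternate read count.
#' @param bg_factor Required ratio of allele fraction to background rate.
#' @return data.table of class `variant_calls`: `chrom`, `pos`, `ref`,
#'   `alt`, `alt_reads`, `depth`, `af`, `b`, `pass_af`, `pass_reads`,
#'   `pass_bg`, `pass`, `filter`.
#' @export
call_variants <- function(pileup, background,
                          min_af = 0.10, min_alt = 5L, bg_factor = 20) {
  long <- data.table::rbindlist(lapply(BASES, function(b) {
    data.table::data.table(chrom = pileup$chrom, pos = pileup$pos,
                           ref = pileup$ref, alt = b,
                           alt_reads = pileup[[b]], depth = pileup$depth)
  }))
  long <- long[alt != ref & alt_reads > 0L]
  calls <- merge(long, background[, c("chrom", "pos", "alt", "b")],
                 by = c("chrom", "pos", "alt"), all.x = TRUE)
  if (anyNA(calls$b)) stop("background model does not cover all pileup sites")
  calls[, af := alt_reads / depth]
  calls[, pass_af := af >= min_af]
  calls[, pass_reads := alt_reads >= min_alt]
  calls[, pass_bg := af >= bg_factor * b]
  calls[, pass := pass_af & pass_reads & pass_bg]
  calls[, filter := ifelse(pass, "PASS",
                           gsub("^;|;$", "", paste0(
                             ifelse(pass_af, "", "lowAF;"),
                             ifelse(pass_reads, "", "lowDepth;"),
                             ifelse(pass_bg, "", "bgRatio;"))))]
  calls[, filter := sub(";$", "", filter)]
  data.table::setorder(calls, chrom, pos, alt)
  data.table::setcolorder(calls, c("chrom", "pos", "ref", "alt", "alt_reads",
                                   "depth", "af", "b", "pass_af", "pass_reads",
                                   "pass_bg", "pass", "filter"))
  data.table::setattr(calls, "class", c("variant_calls", class(calls)))
  calls[]
}

#' Write variant calls as VCF v4.2
#'
#' Both PASS and non-PASS candidates are written; the FILTER column encodes
#' which rule(s) failed (`lowAF`, `lowDepth`, `bgRatio`). Positions are
#' 1-based per the VCF standard.
#'
#' @param calls A `variant_calls` table.
#' @param path Output path.
#' @param sample_id Sample name recorded in the header.
#' @export
write_vcf <- function(calls, path, sample_id = "TUMOR") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FILTER=<ID=lowAF,Description=\"Alternate allele fraction below threshold\">",
           "##FILTER=<ID=lowDepth,Description=\"Fewer alternate reads than required\">",
           "##FILTER=<ID=bgRatio,Description=\"Allele fraction below factor times background error rate\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
           "##INFO=<ID=BG,Number=1,Type=Float,Description=\"Background error rate\">",
           sprintf("##SAMPLE=<ID=%s>", sample_id),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AF=%.6g;BG=%.6g",
                 calls$chrom, calls$pos, calls$ref, calls$alt, calls$filter,
                 calls$depth, calls$af, calls$b)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
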