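# Shared fixtures: a compact reference/panel with the four mandatory
# control chromosomes and one or two 1-kb target genes. Built in code at
# test time; nothing on disk.

tiny_reference <- function(seed = 2, genes = c("GENE1", "GENE2"),
                           gene_len = 1500L, ctrl_len = 2400L) {
  lens <- c(stats::setNames(rep(ctrl_len, 4), c("5", "8", "11", "18")),
            stats::setNames(rep(gene_len, length(genes)), genes))
  build_reference(lens, seed = seed)
}

tiny_panel <- function(ref, genes = c("GENE1", "GENE2"), seed = 3,
                       amplicon_length = 150L, step = 100L) {
  tg <- lapply(genes, function(g) list(chrom = g, start = 201L, end = 1200L))
  names(tg) <- genes
  design_panel(ref, tg, amplicon_length = amplicon_length, step = step,
               controls_per_chrom = 14L, seed = seed)
}

# pick the reference base at a site and one alternate
site_bases <- function(ref, chrom, pos) {
  rb <- substr(as.character(ref[[chrom]]), pos, pos)
  list(ref = rb, alt = setdiff(c("A", "C", "G", "T"), rb)[1])
}

make_snv <- function(ref, chrom, pos, af) {
  b <- site_bases(ref, chrom, pos)
  data.frame(chrom = chrom, pos = pos, ref = b$ref, alt = b$alt, af = af)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# hand-built pileup/background rows for filter boundary tests
manual_pileup <- function(chrom, pos, ref, alt, alt_reads, depth) {
  counts <- stats::setNames(rep(0L, 4), c("A", "C", "G", "T"))
  counts[ref] <- depth - alt_reads
  counts[alt] <- alt_reads
  out <- data.table::data.table(chrom = chrom, pos = pos, ref = ref,
                                A = counts[["A"]], C = counts[["C"]],
                                G = counts[["G"]], T = counts[["T"]],
                                depth = depth)
  data.table::setattr(out, "class", c("pileup", class(out)))
  out[]
}

manual_background <- function(chrom, pos, ref, b) {
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  out <- data.table::data.table(chrom = chrom, pos = pos, ref = ref,
                                alt = alts, b = b, n_samples = 1L)
  data.table::setattr(out, "class", c("background_model", class(out)))
  out[]
}
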