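#' Simulate a sequencing run over an amplicon panel
#'
#' Emulates single-end targeted amplicon sequencing of an FFPE tumour (or a
#' healthy control blood). Per-amplicon read counts are Poisson with mean
#' `depth` scaled by the covering gene's spiked copy ratio; reads start at
#' the amplicon start and run `read_length` bases on the forward strand.
#' Spiked point mutations appear on covering reads with probability equal
#' to the allele fraction; fusion junction reads are emitted at exactly the
#' requested count and always carry at least 30 bases from each partner
#' (the downstream anchor rule needs both ends); sequencing/FFPE noise is an
#' i.i.d. per-base substitution at `base_error_rate`.
#'
#' @param reference `DNAStringSet` from [build_reference()].
#' @param panel `panel_design` from [design_panel()].
#' @param lesions A [lesion_spec()]; empty by default.
#' @param depth Mean per-amplicon read count (> 0).
#' @param read_length Read length; must be >= 60 when fusions are spiked.
#' @param base_error_rate Per-base substitution probability.
#' @param sample_id Sample identifier.
#' @param class `"tumor"` or `"control_blood"`.
#' @param seed Integer seed.
#' @return A list of class `simulated_sample`: `sample_id`, `class`,
#'   `reads` (data.table: `read_id`, `seq`, `chrom`, `start`, `end`,
#'   `origin`), `truth` (the lesion spec plus observability flags),
#'   `base_error_rate`, `read_length`, `seed`.
#' @export
simulate_sample <- function(reference, panel, lesions = lesion_spec(),
                            depth = 200, read_length = 150L,
                            base_error_rate = 0.002,
                            sample_id = "S1",
                            class = c("tumor", "control_blood"),
                            seed = 1L) {
  class <- match.arg(class)
  if (depth <= 0) stop("depth must be positive")
  read_length <- as.integer(read_length)
  if (!is.null(lesions$fusions) && nrow(lesions$fusions) > 0 && read_length < 60L)
    stop("read_length must be >= 60 when fusions are spiked")
  if (class == "control_blood" && !is_empty_lesion(lesions))
    warning("control blood sample carries spiked lesions")

  set.seed(seed)
  chrom_seq <- stats::setNames(as.character(reference), names(reference))
  chrom_len <- stats::setNames(nchar(chrom_seq), names(chrom_seq))

  # copy ratio per amplicon (control amplicons and unlisted genes stay at 1)
  ratio <- rep(1, nrow(panel))
  if (!is.null(lesions$cnvs)) {
    m <- match(panel$gene, lesions$cnvs$gene)
    ratio[!is.na(m)] <- lesions$cnvs$copy_ratio[m[!is.na(m)]]
  }

  counts <- stats::rpois(nrow(panel), depth * ratio)

  # read start per amplicon: amplicon start, shifted left if the read would
  # overrun the chromosome
  rstart <- pmin(panel$start, chrom_len[panel$chrom] - read_length + 1L)
  if (any(rstart < 1L)) stop("chromosome shorter than read_length")
  base_read <- substring(chrom_seq[panel$chrom], rstart, rstart + read_length - 1L)

  reads <- data.table::data.table(
    seq = rep(base_read, counts),
    chrom = rep(panel$chrom, counts),
    start = rep(as.integer(rstart), counts),
    origin = rep(panel$amplicon_id, counts))
  reads[, end := start + read_length - 1L]

  # spike SNVs onto covering reads
  snv_truth <- NULL
  if (!is.null(lesions$snvs) && nrow(lesions$snvs) > 0) {
    snv_truth <- data.table::copy(lesions$snvs)
    snv_truth[, observable := FALSE]
    for (i in seq_len(nrow(snv_truth))) {
      s <- snv_truth[i]
      ref_base <- substr(chrom_seq[[s$chrom]], s$pos, s$pos)
      if (ref_base != s$ref)
        stop("SNV ref base mismatch at ", s$chrom, ":", s$pos,
             " (reference has ", ref_base, ")")
      cover <- which(reads$chrom == s$chrom & reads$start <= s$pos & reads$end >= s$pos)
      if (!length(cover)) {
        warning("SNV at ", s$chrom, ":", s$pos, " overlaps no amplicon; unobservable")
        next
      }
      snv_truth[i, observable := TRUE]
      carry <- cover[stats::runif(length(cover)) < s$af]
      if (length(carry)) {
        offs <- s$pos - reads$start[carry] + 1L
        x <- reads$seq[carry]
        substr(x, offs, offs) <- s$alt   # substr<- recycles elementwise
        reads$seq[carry] <- x
      }
    }
  }

  # fusion junction reads: exact requested count, split point uniform with
  # >= 30 bases on each side
  fus_truth <- NULL
  fus_reads <- NULL
  if (!is.null(lesions$fusions) && nrow(lesions$fusions) > 0) {
    fus_truth <- data.table::copy(lesions$fusions)
    fl <- vector("list", nrow(fus_truth))
    for (i in seq_len(nrow(fus_truth))) {
      f <- fus_truth[i]
      n <- f$n_reads
      if (n == 0) next
      lmin <- 30L; lmax <- read_length - 30L
      lefts <- sample(seq.int(lmin, lmax), n, replace = TRUE)
      seqA <- substring(chrom_seq[[f$chromA]], f$posA - lefts + 1L, f$posA)
      rl <- read_length - lefts
      if (f$orientation == "++") {
        seqB <- substring(chrom_seq[[f$chromB]], f$posB, f$posB + rl - 1L)
      } else {
        raw <- substring(chrom_seq[[f$chromB]], f$posB - rl + 1L, f$posB)
        seqB <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(raw)))
      }
      if (any(nchar(seqA) != lefts) || any(nchar(seqB) != rl))
        stop("fusion breakpoint too close to a chromosome edge for read_length")
      fl[[i]] <- data.table::data.table(
        seq = paste0(seqA, seqB),
        chrom = NA_character_, start = NA_integer_, end = NA_integer_,
        origin = sprintf("junction_%d", i))
    }
    fus_reads <- data.table::rbindlist(fl)
  }

  if (!is.null(fus_reads) && nrow(fus_reads))
    reads <- data.table::rbindlist(list(reads, fus_reads), use.names = TRUE)

  # i.i.d. per-base substitution noise: error flips the base to one of the
  # other three, uniformly
  if (base_error_rate > 0 && nrow(reads) > 0) {
    total <- nrow(reads) * read_length
    n_err <- stats::rbinom(1L, total, base_error_rate)
    if (n_err > 0) {
      idx <- sample.int(total, n_err)
      ri <- (idx - 1L) %/% read_length + 1L
      pi <- (idx - 1L) %% read_length + 1L
      seqs <- reads$seq
      cur <- substring(seqs[ri], pi, pi)
      off <- sample.int(3L, n_err, replace = TRUE)
      newb <- BASES[(match(cur, BASES) - 1L + off) %% 4L + 1L]
      for (k in seq_len(n_err))   # loop: the same read may carry two errors
        substr(seqs[ri[k]], pi[k], pi[k]) <- newb[k]
      reads[, seq := seqs]
    }
  }

  reads[, read_id := sprintf("%s_r%06d", sample_id, seq_len(.N))]
  data.table::setcolorder(reads, c("read_id", "seq", "chrom", "start", "end", "origin"))

  truth <- list(snvs = snv_truth, fusions = fus_truth, cnvs = lesions$cnvs)
  structure(list(sample_id = sample_id, class = class, reads = reads[],
                 truth = truth, base_error_rate = base_error_rate,
                 read_length = read_length, seed = seed,
                 amplicon_counts = stats::setNames(counts, panel$amplicon_id)),
            class = "simulated_sample")
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat(sprintf("simulated_sample %s (%s): %d reads of length %d, error %.4g\n",
              x$sample_id, x$class, nrow(x$reads), x$read_length,
              x$base_error_rate))
  invisible(x)
}

#' Write simulated reads as FASTQ (Phred+33, constant Q30)
#' @param sample A `simulated_sample` (or a data.table with `read_id`, `seq`).
#' @param path Output path.
#' @export
write_fastq <- function(sample, path) {
  reads <- if (inherits(sample, "simulated_sample")) sample$reads else sample
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("?", nchar(reads$seq)))  # '?' = Q30
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read table
#' @param path FASTQ path.
#' @return data.table with `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table::data.table(read_id = sub("\\s.*$", "", names(x)),
                         seq = as.character(x))
}

#' Write a sample's truth record as JSON
#' @param sample A `simulated_sample`.
#' @param path Output path.
#' @export
write_truth_json <- function(sample, path) {
  jsonlite::write_json(
    list(sample_id = sample$sample_id, class = sample$class,
         seed = sample$seed, base_error_rate = sample$base_error_rate,
         truth = sample$truth),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
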