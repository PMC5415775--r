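#' @import data.table
NULL

BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Exact k-mer seed index over a reference
#'
#' Hash from every reference k-mer to its (encoded) positions; the seed
#' stage of [align_reads()] and [align_anchors()]. Build once and pass via
#' their `index` argument when aligning many samples against the same
#' reference.
#'
#' @param reference `DNAStringSet`.
#' @param k Seed length (20 for reads, the anchor length for anchors).
#' @export
ref_kmer_index <- function(reference, k = 20L) {
  seqs <- as.character(reference)
  encs <- character(0); keys <- character(0)
  all_kmers <- list(); all_enc <- list()
  for (ci in seq_along(seqs)) {
    L <- nchar(seqs[ci])
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    all_kmers[[ci]] <- substring(seqs[ci], starts, starts + k - 1L)
    all_enc[[ci]] <- ci * 1e9 + starts
  }
  km <- unlist(all_kmers); en <- unlist(all_enc)
  keep <- !grepl("[^ACGT]", km)
  idx <- list2env(split(en[keep], km[keep]), hash = TRUE)
  structure(list(index = idx, k = k, chroms = names(reference),
                 seqs = seqs, lens = nchar(seqs)),
            class = "kmer_index")
}

count_mismatches <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# place one sequence: unique best ungapped placement or NULL.
# `rc` is the precomputed reverse complement (vectorised upstream).
place_sequence <- function(seq, rc, ki, max_mismatch) {
  L <- nchar(seq)
  k <- ki$k
  if (L < k) return(NULL)
  offsets <- unique(c(seq.int(1L, L - k + 1L, by = k), L - k + 1L))
  no <- length(offsets)
  seeds <- c(substring(seq, offsets, offsets + k - 1L),
             substring(rc, offsets, offsets + k - 1L))
  hits <- mget(seeds, envir = ki$index, ifnotfound = list(NULL))
  nh <- lengths(hits)
  if (!any(nh > 0L)) return(NULL)
  cand <- unlist(hits, use.names = FALSE) -
    rep(rep(offsets - 1L, 2L), nh)        # implied placement of full sequence
  cand_strand <- rep(rep(c("+", "-"), each = no), nh)
  key <- paste0(cand_strand, cand)
  keep <- !duplicated(key)
  cand <- cand[keep]; cand_strand <- cand_strand[keep]

  ci <- floor(cand / 1e9); pos <- cand - ci * 1e9
  ok <- pos >= 1 & pos + L - 1 <= ki$lens[ci]
  if (!any(ok)) return(NULL)
  ci <- ci[ok]; pos <- pos[ok]; strand <- cand_strand[ok]
  nm <- integer(length(ci))
  for (i in seq_along(ci)) {
    target <- if (strand[i] == "+") seq else rc
    nm[i] <- count_mismatches(target, substr(ki$seqs[ci[i]], pos[i], pos[i] + L - 1L))
  }
  ok <- nm <= max_mismatch
  if (!any(ok)) return(NULL)
  ci <- ci[ok]; pos <- pos[ok]; strand <- strand[ok]; nm <- nm[ok]
  best <- min(nm)
  if (sum(nm == best) > 1L) return(NULL)   # ambiguous: drop deterministically
  w <- which.min(nm)
  list(chrom = ki$chroms[ci[w]], pos = as.integer(pos[w]),
       strand = strand[w], nm = nm[w])
}

#' Align panel reads to the reference
#'
#' A deliberately simple seed-and-extend stand-in for a production short-read
#' aligner: exact 20-mer seeds at regular offsets on both strands, ungapped
#' full-length extension with a mismatch budget, and a unique-best rule.
#' Reads with no placement within budget (including fusion-junction reads,
#' which have no contiguous reference origin) and reads whose best placement
#' is tied are reported unaligned.
#'
#' Identical sequences are placed once and the result broadcast, since
#' placement is a pure function of the sequence.
#'
#' @param reads A `simulated_sample` or a data.table with `read_id`, `seq`.
#' @param reference `DNAStringSet`.
#' @param max_mismatch Mismatch budget for a valid placement.
#' @param k Seed length.
#' @param index Optional prebuilt seed index from `ref_kmer_index()`
#'   (reused across samples of the same reference in simulation studies).
#' @return data.table of class `alignments`: `read_id`, `status`
#'   (`"aligned"`/`"unaligned"`), `chrom`, `pos` (1-based leftmost),
#'   `strand`, `nm`, `duplicate`.
#' @export
align_reads <- function(reads, reference, max_mismatch = 5L, k = 20L,
                        index = NULL) {
  if (length(reference) == 0L) stop("empty reference")
  rd <- if (inherits(reads, "simulated_sample")) reads$reads else data.table::as.data.table(reads)
  ki <- if (is.null(index)) ref_kmer_index(reference, k = as.integer(k)) else index

  useq <- unique(rd$seq)
  urc <- revcomp_chr(useq)
  placements <- mapply(place_sequence, useq, urc,
                       MoreArgs = list(ki = ki, max_mismatch = max_mismatch),
                       SIMPLIFY = FALSE, USE.NAMES = FALSE)
  m <- match(rd$seq, useq)
  pl <- placements[m]
  hit <- !vapply(pl, is.null, logical(1))
  out <- data.table::data.table(
    read_id = rd$read_id,
    status = ifelse(hit, "aligned", "unaligned"),
    chrom = NA_character_, pos = NA_integer_, strand = NA_character_,
    nm = NA_integer_, duplicate = FALSE)
  if (any(hit)) {
    out$chrom[hit] <- vapply(pl[hit], `[[`, character(1), "chrom")
    out$pos[hit] <- vapply(pl[hit], `[[`, integer(1), "pos")
    out$strand[hit] <- vapply(pl[hit], `[[`, character(1), "strand")
    out$nm[hit] <- vapply(pl[hit], `[[`, integer(1), "nm")
  }
  data.table::setattr(out, "class", c("alignments", class(out)))
  out[]
}

#' Export alignments to SAM
#'
#' Writes the 11 mandatory SAM columns plus an `NM` tag. Unaligned records
#' get FLAG 4; reverse-strand placements FLAG 16; duplicates add 1024.
#' SAM positions are 1-based, matching the package's internal convention.
#'
#' @param alignments From [align_reads()].
#' @param reads Read table supplying sequences (`read_id`, `seq`).
#' @param reference `DNAStringSet` (for the `@SQ` header).
#' @param path Output path.
#' @export
export_sam <- function(alignments, reads, reference, path) {
  rd <- if (inherits(reads, "simulated_sample")) reads$reads else data.table::as.data.table(reads)
  seqs <- rd$seq[match(alignments$read_id, rd$read_id)]
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), Biostrings::width(reference)))
  flag <- ifelse(alignments$status == "aligned",
                 ifelse(alignments$strand == "-", 16L, 0L), 4L) +
          ifelse(alignments$duplicate, 1024L, 0L)
  aligned <- alignments$status == "aligned"
  # SAM stores the reverse-complement for minus-strand placements
  out_seq <- seqs
  rev <- aligned & alignments$strand == "-"
  if (any(rev)) out_seq[rev] <- revcomp_chr(seqs[rev])
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                 alignments$read_id, flag,
                 ifelse(aligned, alignments$chrom, "*"),
                 ifelse(aligned, alignments$pos, 0L),
                 ifelse(aligned, 60L, 0L),
                 ifelse(aligned, paste0(nchar(seqs), "M"), "*"),
                 out_seq,
                 ifelse(aligned & !is.na(alignments$nm), alignments$nm, 0L))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Import alignments from SAM
#'
#' Reads the 11 mandatory columns of a SAM file. `@SQ` headers must match
#' the reference (same names and lengths). FLAG bit 4 gives unaligned
#' records, bit 16 a reverse-strand placement, bit 1024 the duplicate flag.
#'
#' @param path SAM path.
#' @param reference `DNAStringSet` to validate the header against.
#' @return Same shape as [align_reads()], plus a `seq` column (forward
#'   orientation restored for minus-strand records).
#' @export
import_sam <- function(path, reference) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub(".*\\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\\tLN:([0-9]+).*", "\\1", sq))
  ref_len <- stats::setNames(Biostrings::width(reference), names(reference))
  if (!all(sn %in% names(ref_len)) || !all(ln == ref_len[sn]))
    stop("SAM header @SQ lines do not match the reference")

  rec <- lines[!startsWith(lines, "@")]
  rec <- rec[nzchar(rec)]
  f <- data.table::tstrsplit(rec, "\t", fixed = TRUE, keep = 1:10)
  flag <- as.integer(f[[2]])
  unmapped <- bitwAnd(flag, 4L) > 0L
  minus <- bitwAnd(flag, 16L) > 0L
  dup <- bitwAnd(flag, 1024L) > 0L
  nm <- suppressWarnings(as.integer(sub(".*\\tNM:i:([0-9]+).*", "\\1", rec)))
  nm[!grepl("\tNM:i:", rec)] <- NA_integer_
  sq10 <- f[[10]]
  if (any(minus & !unmapped))
    sq10[minus & !unmapped] <- revcomp_chr(sq10[minus & !unmapped])
  out <- data.table::data.table(
    read_id = f[[1]],
    status = ifelse(unmapped, "unaligned", "aligned"),
    chrom = ifelse(unmapped, NA_character_, f[[3]]),
    pos = ifelse(unmapped, NA_integer_, as.integer(f[[4]])),
    strand = ifelse(unmapped, NA_character_, ifelse(minus, "-", "+")),
    nm = nm, duplicate = dup, seq = sq10)
  if (any(out$status == "aligned" & !out$chrom %in% names(ref_len)))
    stop("SAM record on a chromosome absent from the reference")
  data.table::setattr(out, "class", c("alignments", class(out)))
  out[]
}
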