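#' Build a synthetic reference genome
#'
#' Generates random DNA segments that stand in for the handful of genomic
#' regions a targeted amplicon panel covers. The four control chromosomes
#' (5, 8, 11 and 18 by default) must be present because downstream
#' copy-number normalisation anchors on control amplicons placed there.
#'
#' Coordinates throughout the package are 1-based, closed intervals (the
#' R/Bioconductor convention); BED export converts to 0-based half-open and
#' SAM/VCF export stay 1-based, per those standards.
#'
#' @param lengths Named integer vector: chromosome name -> length in bp.
#'   Must include every chromosome in `control_chromosomes`.
#' @param seed Integer seed; identical seeds give byte-identical sequences.
#' @param base_probs Probabilities for A, C, G, T (uniform by default).
#' @param control_chromosomes Chromosome names reserved for control
#'   amplicons.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
build_reference <- function(lengths, seed,
                            base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            control_chromosomes = c("5", "8", "11", "18")) {
  stopifnot(is.numeric(lengths), length(lengths) >= 1L, all(lengths >= 1))
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)) || any(names(lengths) == ""))
    stop("`lengths` must be uniquely named by chromosome")
  missing_ctrl <- setdiff(control_chromosomes, names(lengths))
  if (length(missing_ctrl))
    stop("reference configuration is missing control chromosome(s): ",
         paste(missing_ctrl, collapse = ", "))
  stopifnot(abs(sum(base_probs) - 1) < 1e-8, length(base_probs) == 4L)

  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(as.integer(lengths), function(L) {
    paste(sample(bases, L, replace = TRUE, prob = base_probs), collapse = "")
  }, character(1))
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- names(lengths)
  attr(ref, "control_chromosomes") <- control_chromosomes
  ref
}

#' Design an amplicon panel over a reference
#'
#' Tiles each target gene with overlapping fixed-length amplicons and places
#' control amplicons on each control chromosome. Control amplicons emulate
#' probes in copy-number-quiet regions and are used to correct for
#' between-sample coverage differences; the panel requires 14-21 of them per
#' control chromosome.
#'
#' @param reference A `DNAStringSet` from [build_reference()].
#' @param target_genes Named list: gene label -> `list(chrom =, start =, end =)`
#'   (1-based closed interval on the reference).
#' @param amplicon_length Amplicon (and default read) length in bp.
#' @param step Tiling step between consecutive amplicon starts.
#' @param controls_per_chrom Number of control amplicons per control
#'   chromosome; scalar or named per-chromosome vector, each in 14..21.
#' @param control_chromosomes Control chromosome names.
#' @param seed Seed controlling control-amplicon placement.
#' @return A `data.table` of class `panel_design` with columns
#'   `amplicon_id`, `chrom`, `start`, `end`, `gene`, `is_control`.
#' @export
design_panel <- function(reference, target_genes,
                         amplicon_length = 150L, step = 100L,
                         controls_per_chrom = 14L,
                         control_chromosomes = c("5", "8", "11", "18"),
                         seed = 1L) {
  stopifnot(length(target_genes) >= 1L, !is.null(names(target_genes)))
  chrom_len <- stats::setNames(Biostrings::width(reference), names(reference))
  amplicon_length <- as.integer(amplicon_length)
  step <- as.integer(step)

  if (length(controls_per_chrom) == 1L)
    controls_per_chrom <- stats::setNames(
      rep(as.integer(controls_per_chrom), length(control_chromosomes)),
      control_chromosomes)
  if (!all(control_chromosomes %in% names(controls_per_chrom)))
    stop("controls_per_chrom must cover every control chromosome")
  n_ctrl <- controls_per_chrom[control_chromosomes]
  if (any(n_ctrl < 14L) || any(n_ctrl > 21L))
    stop("control amplicons per chromosome must be between 14 and 21")

  rows <- list()
  for (g in names(target_genes)) {
    tg <- target_genes[[g]]
    if (!tg$chrom %in% names(chrom_len))
      stop("target gene ", g, " maps to unknown chromosome ", tg$chrom)
    if (tg$end > chrom_len[[tg$chrom]] || tg$start < 1L)
      stop("target gene ", g, " exceeds chromosome bounds")
    glen <- tg$end - tg$start + 1L
    if (glen > chrom_len[[tg$chrom]])
      stop("gene ", g, " longer than its chromosome")
    # tile so that the union of amplicons covers [start, end]
    starts <- seq.int(tg$start, max(tg$start, tg$end - amplicon_length + 1L), by = step)
    if (utils::tail(starts, 1L) + amplicon_length - 1L < tg$end)
      starts <- c(starts, tg$end - amplicon_length + 1L)
    starts <- pmax(1L, starts)
    ends <- pmin(starts + amplicon_length - 1L, chrom_len[[tg$chrom]])
    rows[[g]] <- data.table::data.table(
      amplicon_id = sprintf("%s_amp%03d", g, seq_along(starts)),
      chrom = tg$chrom, start = as.integer(starts), end = as.integer(ends),
      gene = g, is_control = FALSE)
  }

  set.seed(seed)
  for (cc in control_chromosomes) {
    k <- n_ctrl[[cc]]
    L <- chrom_len[[cc]]
    if (L < k * amplicon_length)
      stop("control chromosome ", cc, " too short for ", k, " amplicons")
    # non-overlapping random placement on an evenly partitioned chromosome
    slot <- L %/% k
    offs <- sample.int(max(1L, slot - amplicon_length + 1L), k, replace = TRUE)
    starts <- (seq_len(k) - 1L) * slot + offs
    rows[[paste0("ctrl_", cc)]] <- data.table::data.table(
      amplicon_id = sprintf("chr%s_ctrl%02d", cc, seq_len(k)),
      chrom = cc, start = as.integer(starts),
      end = as.integer(starts + amplicon_length - 1L),
      gene = NA_character_, is_control = TRUE)
  }

  panel <- data.table::rbindlist(rows)
  if (anyDuplicated(panel$amplicon_id)) stop("duplicate amplicon ids")
  if (any(panel$start < 1L) || any(panel$end > chrom_len[panel$chrom]))
    stop("amplicon interval outside reference bounds")
  data.table::setattr(panel, "class", c("panel_design", class(panel)))
  panel[]
}

#' Write / read a panel as 6-column BED
#'
#' The name field encodes `amplicon_id|gene`, with a `CTRL|` prefix for
#' control amplicons. BED uses 0-based half-open coordinates; conversion is
#' handled here.
#'
#' @param panel A `panel_design`.
#' @param path Output path.
#' @export
write_panel_bed <- function(panel, path) {
  name <- ifelse(panel$is_control,
                 paste0("CTRL|", panel$amplicon_id),
                 paste0(panel$amplicon_id, "|", panel$gene))
  bed <- data.table::data.table(
    chrom = panel$chrom, start = panel$start - 1L, end = panel$end,
    name = name, score = 0L, strand = "+")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_bed
#' @param path Path to a BED file written by [write_panel_bed()].
#' @export
read_panel_bed <- function(path) {
  bed <- data.table::fread(path, header = FALSE,
                           col.names = c("chrom", "start", "end", "name", "score", "strand"),
                           colClasses = list(character = c(1, 4, 6)))
  is_control <- startsWith(bed$name, "CTRL|")
  stripped <- sub("^CTRL\\|", "", bed$name)
  parts <- data.table::tstrsplit(stripped, "|", fixed = TRUE)
  panel <- data.table::data.table(
    amplicon_id = parts[[1]],
    chrom = bed$chrom, start = bed$start + 1L, end = bed$end,
    gene = if (length(parts) > 1L) parts[[2]] else NA_character_,
    is_control = is_control)
  panel[is_control == TRUE, gene := NA_character_]
  data.table::setattr(panel, "class", c("panel_design", class(panel)))
  panel[]
}

#' Write a reference to FASTA
#' @param reference `DNAStringSet`.
#' @param path Output path.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' Read a reference from FASTA
#' @param path FASTA path.
#' @export
read_reference_fasta <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}
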