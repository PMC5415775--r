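#' Specify lesions to spike into a simulated sample
#'
#' Bundles the three lesion classes the pipeline must recover: point
#' mutations at a chosen allele fraction, fusion junctions between two
#' genomic breakpoints, and gene-level copy-number changes.
#'
#' @param snvs data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `af` (allele fraction in \[0,1\]); or NULL.
#' @param fusions data.frame with columns `chromA`, `posA`, `chromB`,
#'   `posB`, `orientation` (`"++"` keeps both partners forward; `"+-"`
#'   reverse-complements partner B), `n_reads` (junction read count >= 0),
#'   and optional `geneA`, `geneB` labels; or NULL.
#' @param cnvs data.frame with columns `gene`, `copy_ratio` (> 0); or NULL.
#' @return A list of class `lesion_spec`.
#' @export
lesion_spec <- function(snvs = NULL, fusions = NULL, cnvs = NULL) {
  if (!is.null(snvs)) {
    snvs <- data.table::as.data.table(snvs)
    stopifnot(all(c("chrom", "pos", "ref", "alt", "af") %in% names(snvs)),
              all(snvs$af >= 0 & snvs$af <= 1),
              all(snvs$ref %in% c("A", "C", "G", "T")),
              all(snvs$alt %in% c("A", "C", "G", "T")),
              all(snvs$ref != snvs$alt))
  }
  if (!is.null(fusions)) {
    fusions <- data.table::as.data.table(fusions)
    stopifnot(all(c("chromA", "posA", "chromB", "posB", "n_reads") %in% names(fusions)),
              all(fusions$n_reads >= 0))
    if (is.null(fusions$orientation)) fusions[, orientation := "++"]
    stopifnot(all(fusions$orientation %in% c("++", "+-")))
    if (is.null(fusions$geneA)) fusions[, geneA := NA_character_]
    if (is.null(fusions$geneB)) fusions[, geneB := NA_character_]
  }
  if (!is.null(cnvs)) {
    cnvs <- data.table::as.data.table(cnvs)
    stopifnot(all(c("gene", "copy_ratio") %in% names(cnvs)),
              all(cnvs$copy_ratio > 0))
  }
  structure(list(snvs = snvs, fusions = fusions, cnvs = cnvs),
            class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat("lesion_spec:",
      if (is.null(x$snvs)) 0L else nrow(x$snvs), "SNV(s),",
      if (is.null(x$fusions)) 0L else nrow(x$fusions), "fusion(s),",
      if (is.null(x$cnvs)) 0L else nrow(x$cnvs), "CNV(s)\n")
  invisible(x)
}

is_empty_lesion <- function(lesions) {
  is.null(lesions$snvs) && is.null(lesions$fusions) && is.null(lesions$cnvs)
}
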