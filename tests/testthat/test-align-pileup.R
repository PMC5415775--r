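test_that("error-free reads align at their true origin; junk does not", {
  ref <- tiny_reference()
  panel <- tiny_panel(ref)
  s <- simulate_sample(ref, panel, depth = 15, base_error_rate = 0, seed = 4)
  al <- align_reads(s, ref)
  expect_true(all(al$status == "aligned"))
  expect_identical(al$chrom, s$reads$chrom)
  expect_identical(al$pos, s$reads$start)
  expect_true(all(al$strand == "+"))
  expect_true(all(al$nm == 0L))
  # a read of 150 N's is unalignable
  nn <- data.table::data.table(read_id = "nn", seq = strrep("N", 150))
  expect_identical(align_reads(nn, ref)$status, "unaligned")
  expect_error(align_reads(nn, Biostrings::DNAStringSet()), "empty reference")
})

test_that("reverse-complemented reads are placed on the minus strand", {
  ref <- tiny_reference(genes = "GENE1")
  frag <- substr(as.character(ref[["GENE1"]]), 301, 450)
  rd <- data.table::data.table(read_id = c("f", "r"),
                               seq = c(frag, revcomp(frag)))
  al <- align_reads(rd, ref)
  expect_identical(al$status, c("aligned", "aligned"))
  expect_identical(al$pos, c(301L, 301L))
  expect_identical(al$strand, c("+", "-"))
})

test_that("fusion-junction reads have no contiguous placement (brute-force oracle)", {
  ref <- tiny_reference()
  panel <- tiny_panel(ref)
  fus <- data.frame(chromA = "GENE1", posA = 800L, chromB = "GENE2",
                    posB = 700L, n_reads = 5L)
  s <- simulate_sample(ref, panel, lesion_spec(fusions = fus),
                       depth = 5, base_error_rate = 0, seed = 6)
  al <- align_reads(s, ref)
  jr <- s$reads$read_id[s$reads$origin == "junction_1"]
  expect_true(all(al$status[al$read_id %in% jr] == "unaligned"))
  # oracle: brute-force scan finds nothing within the mismatch budget
  expect_null(brute_force_place(s$reads$seq[s$reads$origin == "junction_1"][1],
                                ref, max_mismatch = 5L))
})

test_that("ambiguous placements are dropped deterministically", {
  set.seed(123)
  seg <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  lens <- c("5" = 2400, "8" = 2400, "11" = 2400, "18" = 2400)
  base <- build_reference(lens, seed = 40)
  # duplicate a 400-bp segment on two chromosomes
  dup <- Biostrings::DNAStringSet(c(as.character(base), rep = paste0(seg, seg)))
  names(dup) <- c(names(base), "dupchr")
  rd <- data.table::data.table(read_id = "amb", seq = substr(seg, 1, 150))
  al <- align_reads(rd, dup)
  expect_identical(al$status, "unaligned")   # exact match at two loci
})

test_that("aligner agrees with the brute-force all-positions oracle", {
  ref <- tiny_reference(genes = "GENE1")
  panel <- tiny_panel(ref, genes = "GENE1")
  set.seed(77)
  s <- simulate_sample(ref, panel, depth = 4, base_error_rate = 0.02, seed = 77)
  al <- align_reads(s, ref)
  idx <- sample(nrow(s$reads), 40)
  for (i in idx) {
    bf <- brute_force_place(s$reads$seq[i], ref, max_mismatch = 5L)
    row <- al[al$read_id == s$reads$read_id[i], ]
    if (is.null(bf) || length(bf) > 1L) {
      expect_identical(row$status, "unaligned")
    } else {
      expect_identical(row$status, "aligned")
      expect_identical(row$chrom, bf[[1]]$chrom)
      expect_identical(row$pos, bf[[1]]$pos)
      expect_identical(row$nm, bf[[1]]$nm)
    }
  }
})

test_that("SAM export/import round-trips and honours flags", {
  ref <- tiny_reference(genes = "GENE1")
  panel <- tiny_panel(ref, genes = "GENE1")
  s <- simulate_sample(ref, panel, depth = 5, base_error_rate = 0.01, seed = 8)
  al <- align_reads(s, ref)
  td <- withr::local_tempdir()
  sam <- file.path(td, "a.sam")
  export_sam(al, s, ref, sam)
  al2 <- import_sam(sam, ref)
  expect_identical(al2$read_id, al$read_id)
  expect_identical(al2$status, al$status)
  expect_identical(al2$chrom, al$chrom)
  expect_identical(al2$pos, al$pos)
  expect_identical(al2$strand, al$strand)
  expect_identical(al2$duplicate, al$duplicate)
  expect_identical(al2$seq[al2$status == "aligned"],
                   s$reads$seq[al$status == "aligned"])

  # hand-written minimal records: FLAG 4 -> unaligned, POS kept 1-based,
  # FLAG 1024 -> duplicate
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(ref), Biostrings::width(ref)),
             "r1\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*",
             "r2\t0\tGENE1\t100\t60\t4M\t*\t0\t0\tACGT\t*",
             "r3\t1024\tGENE1\t7\t60\t4M\t*\t0\t0\tACGT\t*")
  f <- file.path(td, "manual.sam")
  writeLines(lines, f)
  m <- import_sam(f, ref)
  expect_identical(m$status, c("unaligned", "aligned", "aligned"))
  expect_identical(m$pos, c(NA_integer_, 100L, 7L))
  expect_identical(m$duplicate, c(FALSE, FALSE, TRUE))
  # header mismatch rejected
  bad <- c("@SQ\tSN:nope\tLN:55", lines[-(1:7)])
  writeLines(bad, f)
  expect_error(import_sam(f, ref), "match the reference")
})

test_that("pileups count bases correctly (brute-force oracle) and conserve depth", {
  ref <- tiny_reference(genes = "GENE1")
  panel <- tiny_panel(ref, genes = "GENE1")
  s <- simulate_sample(ref, panel, depth = 8, base_error_rate = 0.01, seed = 12)
  al <- align_reads(s, ref)
  pu <- build_pileup(al, s, ref, panel)
  expect_true(all(pu$A + pu$C + pu$G + pu$T == pu$depth))

  # brute-force per-read tally on a 10-read subset at 5 sites
  sub_ids <- s$reads$read_id[1:10]
  al10 <- al[al$read_id %in% sub_ids, ]
  pu10 <- build_pileup(al10, s, ref, panel)
  nonzero <- pu10[pu10$depth > 0, ]
  sites <- nonzero[unique(pmin(c(1, 10, 100, 200, 300), nrow(nonzero))), ]
  for (k in seq_len(nrow(sites))) {
    st <- sites[k, ]
    tally <- stats::setNames(rep(0L, 4), c("A", "C", "G", "T"))
    for (i in which(al10$status == "aligned")) {
      p0 <- al10$pos[i]
      sq <- s$reads$seq[s$reads$read_id == al10$read_id[i]]
      if (al10$chrom[i] == st$chrom && p0 <= st$pos && p0 + nchar(sq) - 1L >= st$pos) {
        b <- substr(sq, st$pos - p0 + 1L, st$pos - p0 + 1L)
        tally[b] <- tally[b] + 1L
      }
    }
    expect_identical(unlist(st[, c("A", "C", "G", "T")]), tally)
  }

  # 50 identical error-free reads covering a site -> depth 50, ref count 50
  frag <- substr(as.character(ref[["GENE1"]]), 301, 450)
  rd <- data.table::data.table(read_id = sprintf("r%02d", 1:50),
                               seq = rep(frag, 50))
  al50 <- align_reads(rd, ref)
  pu50 <- build_pileup(al50, rd, ref, panel)
  site <- pu50[pu50$chrom == "GENE1" & pu50$pos == 350, ]
  expect_identical(site$depth, 50L)
  expect_identical(site[[site$ref]], 50L)

  # dedupe never increases depth
  al50$duplicate[1:10] <- TRUE
  pu_d <- build_pileup(al50, rd, ref, panel, dedupe = TRUE)
  pu_n <- build_pileup(al50, rd, ref, panel, dedupe = FALSE)
  expect_true(all(pu_d$depth <= pu_n$depth))
  expect_identical(pu_d[pu_d$chrom == "GENE1" & pu_d$pos == 350, ]$depth, 40L)
})

test_that("background model averages control allele fractions with a floor", {
  # two controls with alt fractions 0.002 and 0.004 at a site -> b = 0.003
  p1 <- manual_pileup("GENE1", 500L, "A", "G", 2L, 1000L)   # 0.002
  p2 <- manual_pileup("GENE1", 500L, "A", "G", 4L, 1000L)   # 0.004
  bg <- estimate_background(list(p1, p2))
  expect_equal(bg[bg$alt == "G", ]$b, 0.003)
  expect_equal(bg[bg$alt == "C", ]$b, 1e-4)   # error-free alt floored
  expect_identical(unique(bg$n_samples), 2L)
  expect_error(estimate_background(list()), "at least one")

  # all controls error-free -> b = floor everywhere
  p0 <- manual_pileup("GENE1", 500L, "A", "G", 0L, 800L)
  bg0 <- estimate_background(list(p0))
  expect_true(all(bg0$b == 1e-4))

  # simulation oracle: mean background over 5 controls at error e matches
  # e/3 per alternate base within 3 SE. e is kept small so the aligner's
  # mismatch budget censors essentially no reads (at large e dropping
  # error-rich reads deflates the observed fraction).
  ref <- tiny_reference(genes = "GENE1")
  panel <- tiny_panel(ref, genes = "GENE1")
  e <- 0.005
  ki <- ref_kmer_index(ref)
  pus <- lapply(1:5, function(i) {
    s <- simulate_sample(ref, panel, depth = 150, base_error_rate = e,
                         sample_id = paste0("C", i), class = "control_blood",
                         seed = 100 + i)
    build_pileup(align_reads(s, ref, index = ki), s, ref, panel)
  })
  bg5 <- estimate_background(pus, floor = 0)   # unfloored: unbiased mean
  m <- mean(bg5$b)
  se <- stats::sd(bg5$b) / sqrt(nrow(bg5))
  expect_lt(abs(m - e / 3), 3 * se + 1e-5)
})

test_that("variant filter boundary cases match the published rule exactly", {
  # f = 0.10, a = 5, b = 0.001 -> PASS (all three rules inclusive)
  pu <- manual_pileup("GENE1", 500L, "A", "G", 5L, 50L)
  bg <- manual_background("GENE1", 500L, "A", 0.001)
  v <- call_variants(pu, bg)
  expect_true(v$pass)
  expect_identical(v$filter, "PASS")

  # a = 4, f = 0.40 -> fails the read-support rule only
  v2 <- call_variants(manual_pileup("GENE1", 500L, "A", "G", 4L, 10L), bg)
  expect_false(v2$pass)
  expect_identical(v2$filter, "lowDepth")

  # f = 0.15 < 20 * b = 0.2 -> fails the background rule only
  v3 <- call_variants(manual_pileup("GENE1", 500L, "A", "G", 15L, 100L),
                      manual_background("GENE1", 500L, "A", 0.01))
  expect_false(v3$pass)
  expect_identical(v3$filter, "bgRatio")

  # uncovered site errors out
  expect_error(call_variants(manual_pileup("X", 1L, "A", "G", 3L, 10L), bg),
               "cover")
})

test_that("filter thresholds are monotone and clean samples yield no PASS", {
  pu <- data.table::rbindlist(list(
    manual_pileup("G", 1L, "A", "C", 6L, 40L),
    manual_pileup("G", 2L, "A", "G", 12L, 60L),
    manual_pileup("G", 3L, "A", "T", 3L, 12L),
    manual_pileup("G", 4L, "C", "T", 30L, 100L)))
  bg <- data.table::rbindlist(lapply(1:4, function(p)
    manual_background("G", p, c("A", "A", "A", "C")[p], 0.004)))
  base_pass <- sum(call_variants(pu, bg)$pass)
  for (af in c(0.1, 0.2, 0.4)) for (ma in c(5L, 10L)) for (bf in c(20, 60)) {
    n <- sum(call_variants(pu, bg, min_af = af, min_alt = ma, bg_factor = bf)$pass)
    expect_lte(n, base_pass)
    # tightening any single threshold from the default never increases PASS
  }
  # error-free lesion-free tumour: zero PASS for any min_alt >= 1
  ref <- tiny_reference(genes = "GENE1")
  panel <- tiny_panel(ref, genes = "GENE1")
  s <- simulate_sample(ref, panel, depth = 60, base_error_rate = 0, seed = 3)
  al <- align_reads(s, ref)
  pu0 <- build_pileup(al, s, ref, panel)
  bg0 <- estimate_background(list(pu0))
  expect_identical(sum(call_variants(pu0, bg0, min_af = 0, min_alt = 1L,
                                     bg_factor = 0)$pass), 0L)
})

test_that("a spiked SNV is recovered as the single PASS call in its gene", {
  ref <- tiny_reference(genes = "GENE1")
  panel <- tiny_panel(ref, genes = "GENE1")
  ki <- ref_kmer_index(ref)
  ctrl <- lapply(1:5, function(i) {
    s <- simulate_sample(ref, panel, depth = 200, base_error_rate = 0.002,
                         sample_id = paste0("C", i), class = "control_blood",
                         seed = 900 + i)
    build_pileup(align_reads(s, ref, index = ki), s, ref, panel)
  })
  bg <- estimate_background(ctrl)
  snv <- make_snv(ref, "GENE1", 655L, af = 0.3)
  s <- simulate_sample(ref, panel, lesion_spec(snvs = snv), depth = 200,
                       base_error_rate = 0.002, seed = 42)
  pu <- build_pileup(align_reads(s, ref, index = ki), s, ref, panel)
  calls <- call_variants(pu, bg)
  hits <- calls[calls$pass == TRUE & calls$chrom == "GENE1", ]
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$pos, 655L)
  expect_identical(hits$alt, snv$alt)
  td <- withr::local_tempdir()
  write_vcf(calls, file.path(td, "calls.vcf"))
  vcf <- readLines(file.path(td, "calls.vcf"))
  expect_true(any(grepl("^##fileformat=VCFv4.2", vcf)))
  expect_true(any(grepl(sprintf("GENE1\t%d\t.\t%s\t%s", 655L, snv$ref, snv$alt),
                        vcf, fixed = FALSE)))
})
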