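# isomiRseq

Canonical miRNA and isomiR profiling from small RNA sequencing reads.

Bulk small-RNA libraries from tumor tissue carry, for each miRNA locus,
not just the canonical mature sequence deposited in miRBase but a cloud of
sequence isoforms — isomiRs — that differ by 5′/3′ end shifts, templated
3′ extensions, non-templated 3′ tails (adenylation/uridylation) and
internal substitutions. Because 5′ shifts move the seed (nucleotides 2–8),
they can retarget a miRNA entirely, so differential-abundance analysis at
isomiR resolution can reveal regulation that canonical-level counting
hides. `isomiRseq` is aimed at analysts profiling small cohorts of graded
tumor samples (e.g. low- vs high-grade chondrosarcoma) who need that
resolution with a fully auditable pipeline.

## What it does

* **Reference model** — hairpin precursor FASTA plus a mature-coordinate
  table (0-based half-open; miRBase GFF3 reader included); RNA or DNA in,
  DNA stored.
* **Offset-aware alignment** — each read is placed directly on a hairpin
  by enumerating every admissible decomposition into a templated body
  (5′ offset within ±4 nt of the mature start, 3′ offset within ±5 nt of
  the mature end, ≤2 substitutions) plus a non-templated 3′ tail (≤3 nt),
  minimizing `(substitutions, tail length, |offset5| + |offset3|)` with
  deterministic tie-breaking. Contaminant reads (rRNA/tRNA/snoRNA/piRNA
  fragments) are removed by decoy matching beforehand.
* **isomiR classification and naming** — classes `3` (3′ variation), `5`
  (5′ shift), `53` (both), `0` (substitution only); dotted names on the
  grammar `{parent}.{class}.P{substitutions}.S.{serial}`, e.g.
  `hsa-miR-451a.3.P0.S.2`, with serials assigned by abundance rank so
  names are reproducible.
* **Quantification** — count matrices at canonical and isomiR level, CPM
  normalization within the miRNA compartment, a 0.001 % mean-expression
  floor, and per-group pooled abundance shares.
* **Differential abundance** — for two groups A (reference) and B:
  per-feature effect size `log2FC = log2(mean CPM_B / mean CPM_A)`;
  features with mean CPM < 10 across all samples discarded; a
  negative-binomial exact test (conditional on each feature's total
  count, small-probability summation) with common and tagwise dispersion
  estimated by conditional maximum likelihood on library-size-equalized
  counts; Benjamini–Hochberg FDR; "strong modulation" selection at
  |log2FC| > 2 and significance at FDR < 0.1.
* **Cross-cohort concordance** — each discovery feature is classified in
  a validation cohort as `not_expressed`, `no_difference`
  (|log2FC| < 0.5), `confirmed` (same sign) or `opposite`.
* **Synthetic cohorts** — a generator emitting FASTQ reads with per-read
  ground truth (locus, isomiR class, offsets, tails, substitutions,
  contaminants) under the same negative-binomial count model, so every
  stage is testable end-to-end without external data.
* **Over-representation** — hypergeometric upper-tail tests of feature
  sets against GMT gene-set files.

## Worked example

Simulate a 2-vs-3 cohort, run the pipeline, and look at the strongly
modulated canonical miRNAs:

```r
library(isomiRseq)

config <- list(
  simulate = TRUE,
  sim = list(n_group_A = 2, n_group_B = 3, n_mirnas = 30,
             library_size_mean = 5000, dispersion = 0.1,
             de_fraction = 0.1, de_log2fc_range = c(3, 4), seed = 41))
res <- run_pipeline(config, "run1")

res$strong_canonical[, c("feature_id", "mean_cpm_A", "mean_cpm_B",
                         "log2fc", "fdr_bh", "direction")]
```

```
  feature_id mean_cpm_A mean_cpm_B   log2fc       fdr_bh direction
1 sim-miR-18   3814.042   46673.96 3.613225 1.672219e-15        up
2 sim-miR-24   5304.092   61353.57 3.531970 1.672219e-15        up
3 sim-miR-22   4197.968   28566.32 2.766552 7.517210e-10        up
```

Each row is a miRNA whose group-B group-mean CPM differs from group A by
more than 4-fold (|log2FC| > 2); `fdr_bh < 0.1` marks it significant
under the exact test. The three loci reported are exactly the three the
generator injected with |log2FC| ∈ [3, 4] (observed log2FC deviates from
the injected value by sampling noise and the compositional shift CPM
normalization introduces when abundant loci change). `run1/` also
contains the isomiR catalog (1709 distinct sequences here, 1681 of them
non-canonical isomiRs), both count matrices, per-sample QC tallies,
abundance shares and an md5 manifest; `render_reports("run1")` draws the
figures from those tables.

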