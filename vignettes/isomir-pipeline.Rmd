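---
title: "Models and methods behind isomiRseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind isomiRseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRseq)
```

# Scope and data model

`isomiRseq` takes short small-RNA reads to differential-abundance tables
at two resolutions: canonical mature miRNAs and individual isomiRs. All
coordinates are 0-based half-open on the hairpin precursor; a mature arm
is a slice `[start, end)` of its hairpin, and its seed is mature
nucleotides 2–8. RNA (`U`) and DNA (`T`) input are both accepted and
stored as DNA, since references ship as RNA while sequencers emit DNA.
The miRBase GFF3 dialect (1-based inclusive) is converted at the I/O
boundary; the 5-column TSV is the canonical internal format so the full
reference never needs to be downloaded for testing.

# Read placement on hairpins

Reads are aligned directly to hairpin precursors rather than to a genome.
The genome pass in a conventional small-RNA pipeline serves mainly to
exclude non-miRNA small RNAs; that role is preserved by an explicit decoy
filter (reads matching any decoy subsequence with at most 1 substitution
and no indels are discarded and tallied).

Each surviving read is decomposed as

* a **templated body** starting at `mature_start + offset5`
  (|offset5| ≤ 4) and ending at `mature_end + offset3` (|offset3| ≤ 5),
  with at most 2 internal substitutions and no indels, plus
* an optional **non-templated 3′ tail** of up to 3 bases.

Every admissible `(mature, offset5, tail length)` combination is
enumerated and the candidate minimizing the score key
`(n_subst, tail_len, |offset5| + |offset3|)` is chosen; remaining ties
break by smaller |offset5|, then lexicographically smallest mature id,
then `offset5`, then `offset3`, so placement is fully deterministic. Two
consequences are worth spelling out:

* **Templated wins over tail.** A 3′ base that matches the hairpin is
  always interpreted as templated extension, never as tail, because tail
  length is minimized before the offset term. This makes the
  decomposition unique.
* **No internal indels.** End shifts and substitutions describe the
  variation the model targets; allowing internal indels would make the
  decomposition non-unique. 5′ variation is therefore represented purely
  as a start-offset change.

The bounds (±4/±5/3 tail/2 substitutions) are exposed via
`align_params()`. They are the package's own defaults — generous enough
to admit the 1–3 nt end variation and 1–2 nt 5′ shifts the isomiR classes
describe, tight enough that random 15–40 nt reads rarely place. The
enumeration is exhaustive within these bounds, so the implementation is
validated against an independent brute-force decomposer in the test
suite (property test over 1000 random reads).

Multi-mapping is resolved best-hit with the deterministic tie-break
above. The insert length window is 15–40 nt: the lower bound sits below
a 20–40 nt library window so that 3′-trimmed isoforms of short (20 nt)
miRNAs are not lost.

# isomiR classes and names

Classes partition non-canonical calls by which end varies: `3` (3′
offset and/or non-templated tail), `5` (5′ offset only), `53` (both),
and `0` for substitution-only variants (no printed precedent exists for
that case; a code is required for totality). Tails count as 3′
variation, not substitutions, matching the 5′/3′ dichotomy. A call is
canonical iff both offsets are zero, the tail is empty and there are no
substitutions; `seed_altered` flags any 5′ shift or substitution in
mature positions 2–8.

Names follow `"{parent}.{class}.P{n_subst}.S.{serial}"`, e.g.
`hsa-miR-451a.3.P0.S.57`. The grammar's `P` field counts internal
substitutions and `S` separates the per-parent serial. The serial is
assigned by rank (total multiplicity descending, ties by sequence), which
makes naming deterministic within and across runs on identical input;
that assignment rule is this package's convention, and the whole grammar
lives behind `assign_names()`/`parse_isomir_name()` so an alternative
scheme can be swapped in.

# Quantification

Library size is the per-sample total of miRNA-assigned counts — not raw
reads — so CPM and percentage shares are computed within the miRNA
compartment and shares sum to 100 % across miRNAs. Canonical-level
counting credits a mature with all of its reads (canonical + isomiRs) by
default; `strict = TRUE` restricts to exact canonical sequences.
Group-level abundance shares use pooled group counts (the share of a
feature in the group total), with mean-of-per-sample-shares available as
a sensitivity alternative. The expression floor keeps a feature when its
mean over all samples of `count/library × 100` exceeds 0.001 %; it is
computed on the miRNA-assigned compartment, after contaminant removal.

# Differential abundance

The reported effect size is `log2(mean CPM_B / mean CPM_A)` with
arithmetic group means and, by default, no pseudocount — the arithmetic
of the published per-feature tables, reproduced digit-for-digit in the
test suite. Features with a zero group mean are flagged infinite rather
than silently dropped. The exact test supplies only p-values and FDR;
its internal fold-change is never reported.

Features with mean CPM < 10 over all samples are discarded before
testing. The test itself is a from-scratch negative-binomial exact test:

1. **Equalization.** Counts are quantile-adjusted to the geometric-mean
   library size: each observation is mapped through its mid-P cumulative
   probability under NB(μ_in, φ) to the matching quantile at μ_out.
   Equal libraries pass through unchanged. (Direct CPM-style rescaling
   would distort the variance the test assumes.)
2. **Dispersion.** The NB parameterization is `var = μ + φμ²`. The
   common φ maximizes the across-feature mean conditional log-likelihood
   (Robinson–Smyth conditional likelihood for equal library sizes,
   summed over both groups) evaluated on a 60-point log grid over
   φ ∈ [10⁻⁶, 10] and interpolated by spline; estimation and
   equalization are iterated twice. Tagwise φ maximizes
   `CL_feature(φ) + prior_df × mean CL(φ)` with `prior_df = 10` by
   default — the named estimator is tagwise, but no published tuning
   value exists to copy, so the default is validated by simulation
   (Poisson data recover φ ≤ 0.05; φ = 0.4 data recover within
   [0.25, 0.60]; `prior_df → ∞` collapses tagwise onto common within
   10⁻⁶).
3. **Test.** Conditional on a feature's total count `z`, the group-A sum
   follows the convolution `NB(n_A μ, size n_A/φ)` against
   `NB(n_B μ, size n_B/φ)` with `μ = z/(n_A+n_B)`. The two-sided p-value
   sums the probabilities of all splits at most as probable as the one
   observed (small-probability summation; the doubling convention is not
   used). As φ → 0 this reduces exactly to the conditional binomial
   test, which the test suite verifies to 10⁻¹⁰ for all totals ≤ 200.

BH adjustment is `stats::p.adjust(method = "BH")`. Strong modulation is
|log2FC| > 2 (strict), significance FDR < 0.1 — both configurable.

Cross-cohort concordance classifies each discovery feature in a
validation cohort, in this fixed order: `not_expressed` (fails the
validation expression threshold), `no_difference` (validation
|log2FC| < 0.5), `confirmed` (sign agrees), `opposite`.

Over-representation of feature sets is the hypergeometric upper tail
P(X ≥ found) with population = universe, successes = set ∩ universe,
draws = query, BH-adjusted across sets — a generic stand-in for
pathway-database statistics whose exact internals are not public.

# The synthetic cohort generator

The generator emulates the structure the analysis assumes, with defaults
chosen as the study conditions of a small graded-tumor cohort:

* **Design**: 2 vs 7 samples (configurable), 50 loci by default
  (20–300 is the intended regime).
* **Counts**: NB with `var = μ + φμ²`, default φ = 0.2 (typical for
  small human cohorts); per-sample library sizes normal with CV 0.2.
* **Skew**: locus 1 holds 30 % of counts by default (a dominant miRNA
  holding 15–50 % of a sample is the observed regime in cartilage
  tumors); the remaining mass is log-normal (sdlog 1.5) across loci,
  giving the heavy-tailed abundance spectrum real libraries show.
* **Effects**: a `de_fraction` of non-dominant loci get group-B means
  scaled by `2^log2FC`, |log2FC| drawn from `de_log2fc_range`
  (default [2.5, 4]; the lower bound must exceed the strong-modulation
  threshold of 2 by construction).
* **isomiR structure** per read: canonical 0.25, 3′ trim 0.30, 3′
  templated extension 0.15, non-templated 3′ tail 0.10, 5′ shift 0.05,
  internal substitution 0.15. No published per-class frequency table
  exists; these defaults encode the qualitative ranking (3′ variation
  dominant, 5′ shifts rare and seed-critical, substitutions common) and
  are fully configurable — they are not claimed as any study's truth.
* **5′ shifts** are start-offset changes of ±1–2 nt; the reference
  generator templates `CC` immediately upstream of every mature so a 5′
  extension inserts C's, the variant form reported for seed-shifted
  isomiRs of miR-142-5p and relatives.
* **Sequencing error** 0.001/base; **contaminants** 5 % of reads, drawn
  as 20–30 nt substrings of a synthetic decoy pool standing in for the
  rRNA/tRNA/snoRNA compartment.

Two generator constraints exist so that the zero-error closure property
is exact rather than approximate, both forced by the aligner's parsimony
rule: internal substitutions avoid the first base and the last
`max_tail + 1` bases (a substitution nearer the 3′ end is, by minimal
score, indistinguishable from a trim-plus-tail), and the first base of a
non-templated tail is drawn to differ from the templated hairpin base
(otherwise it would be a templated extension). Sequencing errors respect
no such constraints — with error enabled, a small fraction of reads
legitimately misalign or reclassify, which is the realistic behavior.

## What passing the synthetic suite does and does not show

The generator produces reads whose only deviations from the reference
are the modeled ones. Real libraries additionally contain adapter
read-through, quality-dependent error profiles, cross-mapping between
paralogous miRNA families, RNA editing, and partially degraded longer
RNAs. Passing closure and recovery tests therefore demonstrates the
pipeline's internal correctness — counts are conserved, decompositions
are minimal-score, the test is calibrated — not that any particular
biological cohort would be analyzed without error. Cohort-level counts
from real data (total expressed miRNAs, isomiR catalog sizes,
validation splits) depend on the deposited libraries and are out of
desk-scale reach; the suite covers the procedures that produce them.

# Numerical and design choices

* **CPM fold-changes are compositional.** Scaling one abundant locus
  changes every other locus's CPM; with a 26 %-share locus dropping
  8-fold, null loci shift by ≈ +0.4 log2 units. The Monte-Carlo
  fold-change recovery test asserts on the replicate mean for this
  reason, and analysts should expect |log2FC| of minor loci to absorb
  part of any large compositional change. No between-sample
  normalization (e.g. TMM) is applied, because plain CPM means are the
  reported quantity.
* **Boundary conventions**: strong modulation is a strict inequality
  (log2FC = 2.0 is not selected); the CPM floor keeps mean CPM ≥ 10;
  the p-value tie tolerance is a relative 10⁻⁷, matching the
  small-probability summation convention of the reference
  implementation of the exact test.
* **Zero handling**: zero-library samples are dropped from CPM with a
  warning; a zero feature total gives p = 1; an all-zero matrix yields
  φ = 0 with a warning.
* **Problem sizes in the suite** (the package's own desk-scale choices):
  read-level simulations use library sizes of 10³–10⁴ reads across 4–5
  samples; count-level calibration uses 5000 features × 10 samples at
  10⁶ library size; the alignment property test uses 1000 random reads
  against 5 hairpins.
* **Determinism**: every stochastic stage is seeded from a single
  integer; the pipeline writes an md5 manifest and two runs with the
  same seed are byte-identical.

# Known limitations

* Hairpin-space alignment cannot detect isomiRs of loci absent from the
  reference, and no novel-miRNA discovery is attempted.
* Best-hit assignment with deterministic tie-breaks can systematically
  favor the lexicographically smaller member of a perfect paralog pair;
  the fractional-assignment alternative is not implemented.
* The exact test covers two-group designs only; no covariates, no GLM.
* Substitution-only isomiRs at the extreme 3′ end are reported as
  trim-plus-tail variants — an identifiability limit of the
  decomposition model, not a bug; the affected calls remain in class
  `3` rather than `0`.
* The dispersion estimator's grid floor (10⁻⁶) means "Poisson" is
  reported as a very small positive φ.
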