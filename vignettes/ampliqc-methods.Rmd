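---
title: "Benchmarking amplicon exome call sets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking amplicon exome call sets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliqc)
```

## The problem

Amplicon-based exome sequencing on semiconductor (flow-space) platforms
delivers fast, cheap exomes but with a characteristic error profile:
SNP calling is accurate, while small indels suffer a high false-positive
rate, concentrated in homopolymer and short-repeat contexts and largely
run-specific. Evaluating such call sets requires (i) putting caller and
truth variants into one canonical representation, (ii) exact allele-level
comparison inside regions where the truth set is reliable, (iii) a
characterization of what the false calls look like, and (iv) hard filters
on the caller's own annotations that discard as many false positives as
possible while retaining a guaranteed fraction of true positives.
`ampliqc` implements that pipeline, plus the coverage analyses that
surround it (amplicon GC dropout, hard-to-sequence exons, downsampling
titrations), and a synthetic-cohort generator so every stage can be
exercised and verified without any external data.

## Normalization and matching

All interval math uses one internal convention: 0-based half-open
coordinates (BED semantics), with VCF positions converted at module
boundaries. Call sets are normalized by splitting multiallelic records
(each split record keeps `n_original_alts`, the alt count of its source
line, and receives its own slice of per-allele annotations) and by
left-aligning indels: shared trailing bases are trimmed, extending left
through the reference when an allele would empty, then shared leading
bases are trimmed while both alleles keep two or more bases, iterated to
a fixed point. The result is the minimal representation at the left-most
equivalent position with one anchor base. Two properties are enforced by
tests: applying the original and the normalized edit to the reference
yields identical haplotypes, and normalization is idempotent. An
independent check against `bcftools norm` on a generated fixture guards
the contract.

Matching is deliberately strict: a call is a true positive iff a truth
record has the same `(chrom, pos, ref, alt)` key after normalization, and
region membership is decided by the POS anchor alone. SNPs and indels
are benchmarked separately; equal-length multi-base substitutions are
excluded from both classes. Genotype (zygosity) is ignored — the
benchmark is allele-level, and `GQ` is parsed only as a filter
parameter. Degenerate denominators are pinned down: an empty evaluated
truth set is an error (it means the region chain is wrong), and a call
set with no calls reports precision 1, FDR 0, F1 0 with a warning.

## Coverage statistics and downsampling

A depth track follows bedGraph semantics; target bases the track does
not span count as depth zero. The summary statistics are mean coverage,
`breadth_k` (fraction of target bases at depth ≥ k, k = 20 by default),
uniformity (fraction at depth ≥ 20 % of the mean), and the IQR of base
depth. Quantiles use the median-unbiased convention (`type = 8`), a
choice the output metadata records since no convention is canonical.

Reads are assigned to amplicons by maximal overlap with ties to the
left-most amplicon — a deterministic proxy for amplicon-primary
assignment. Amplicon GC classes use the conventional cut-offs (high
> 0.75, low < 0.25). Hard-to-sequence exons are those failing a rule in
*every* cohort sample: mean depth < 10 reads (always-low), or covered
fraction below 0.5 / 0.25 / 0.1 (nested partial classes).

Downsampling keeps each read independently with
p = target mean / current mean and recomputes depth from the retained
reads. Variant callability after thinning is emulated, not re-called: a
truth variant is lost iff its post-thinning site depth falls below 20,
the same threshold anchoring the breadth statistic. The titration series
is fitted with `breadth(mean) = 1 − exp(−(mean − m0)/τ)` (predictions
clipped to [0, 1]; fitted on the observed levels only, no extrapolation
claims) and `loss(breadth) = a + b·breadth` by ordinary least squares,
each with r². A constant series yields `NA` r² rather than a fabricated
fit.

## Filter derivation

Five caller parameters per class drive the filters — SNPs: GQ, FDP,
QUAL, STB, FAO; indels: GQ, FDP, QUAL, HRUN, FAO. Removal is the OR of
one-sided failing conditions (`GQ < gq_min`, …, `STB > stb_max` /
`HRUN > hrun_max`): a call must clear every threshold to survive. The
combination logic is a design choice; the one-sided column semantics of
the shipped presets make OR-removal the only reading consistent with
monotone stringency. Calls missing a required parameter can never pass
and are tagged `ts_missing`, counted separately.

Threshold candidates per parameter are the deciles of the training TP
distribution, any preset thresholds, and an always-permissive sentinel
(±∞), which guarantees a feasible solution at 100 % retention. The
search is exhaustive over the five-way candidate grid but runs in
O(grid) time: each call is binned by how many candidates it passes per
parameter, and retained counts for *all* combinations are obtained with
a five-dimensional suffix cumulative sum. A test pins this against
naive enumeration. Among feasible combinations (training TP retention ≥
target) the one maximizing FP removal wins; ties break toward higher TP
retention, then toward more permissive thresholds in the fixed order
GQ, FDP, QUAL, HRUN/STB, FAO, making the result deterministic.
Retention is enforced pooled across the training calls (a per-sample
variant would need per-sample labels; the pooled rule is what the
shipped tooling uses). Presets targeting 99/95/90 % retention
(low/medium/high stringency) ship as a plain-text config — they are
data, not constants, and users can replace the file.

Advisory indel flags never remove calls: `multiallelic_suspect`
(≥ 3 alternate alleles in the source record), `long_indel_suspect`
(indel length > 100 bp), `homopolymer_context` (HRUN ≥ 5).

## The synthetic cohort generator

The generator emulates the statistical structure of an amplicon exome
experiment on a flow-space platform, not its raw data. One synthetic
chromosome is partitioned into one block per exon; each block's base
composition follows its GC class (defaults: 5 % high-GC at ~0.88,
3 % low-GC at ~0.12, the rest balanced), and homopolymer runs (≥ 6 bp)
plus triplet repeats are planted in mid-GC exon interiors — the contexts
where flow-space chemistry actually errs. Exons (120–300 bp) are tiled
by one amplicon when they fit the allowed span (156–240 bp) and by two
overlapping amplicons otherwise. Targets are the amplicon union; the
high-confidence set trims 5 bp from each target interval end.

The default truth composition scales a gold-standard exome truth set's
~49:1 SNP:indel ratio to 1000 variants (980 SNPs, 20 indels). Candidate
variant positions sit on a 10 bp-strided grid over high-confidence ∩
CDS, shuffled once and consumed by truth, recurrent-FP pool and
per-sample unique FPs in turn, so keys never collide even after
left-alignment (records are normalized at creation and collisions
re-drawn).

Error structure, all configurable and all realized values verified by
the test suite against their binomial bands:

* **False negatives.** Per-class rates (defaults 3 % SNP, 30 % indel,
  matching the platform's weak indel sensitivity); a configured fraction
  (default 0.33, the midpoint of the 26–41 % range reported for SNPs)
  placed at sites the sample covers with < 10 reads.
* **False positives.** A per-sample count per class mixes a cohort-wide
  recurrent pool with sample-specific draws. The configured value is the
  *realized* fraction of distinct cohort FPs seen in exactly one sample
  (default 0.71); the generator solves internally (by `uniroot`) for the
  per-sample unique share that produces that expectation given the pool
  inclusion probability (0.9) and cohort size. A configured fraction of
  FP indel records (default 0.10) is emitted multiallelic with three
  insertion alts of increasing length — the homopolymer
  multiple-allele error mode.
* **Annotations.** Class-conditional log-normal/beta families: FPs sit
  at low GQ/QUAL/FAO, strand bias pushed toward 1, elevated HRUN for
  indels; TPs complementary, with FAO drawn binomially from FDP at a
  het-like allele fraction. The hyper-parameters live in the config
  (`default_annotation_params()`), chosen so the classes overlap enough
  that threshold tuning is a genuine trade-off rather than a separable
  toy.
* **Coverage.** Reads span their amplicon; expected counts scale with
  `exp(−strength · penalty(GC))`, the penalty rising linearly above GC
  0.6 and zero below (low-GC amplicons show no bias on this chemistry),
  normalized so expected genome-wide mean coverage equals the configured
  value (default 100×).

Every stage derives an independent stream from the master seed, so the
same configuration is byte-reproducible, samples are independent, and a
sample can be regenerated standalone. The generator emits a sidecar
label table; benchmark results must (and, by test, do) reproduce those
labels exactly, which is what makes the generator an oracle for the
matching machinery.

What the generator does **not** emulate: read sequences, base qualities,
flow-space signal, alignment artifacts, systematic reference bias, or
truth-set errors. Passing tests therefore demonstrate that the
*machinery* is correct and that filters behave as designed under the
modelled error structure — not that any particular real dataset will
show the same FDRs or retention/removal trade-offs.

## Problem sizes and numerical choices

The filter-derivation benchmark uses `tuning_training_config()`: one
pooled training sample with ~10,000 true positives and ~2,000 false
positives per class on a 4 Mb / 4,000-exon design — per-class call
volumes chosen so both classes train on comparable data (this
intentionally overrides the SNP-dominated default composition). Module
tests run on a 0.6 Mb / 240-exon cohort. Curve-fit parameter recovery
uses 10-level series; thinning statistics use 100 replicates. Exact
comparisons are asserted to 1e-9; stochastic realizations against
binomial 99 % bands.

Known limitations: matching has no haplotype-aware rescue (a truth
variant represented as two non-identical normalized records counts as
FN + FP, as exact-key matching dictates); MNP decomposition and phasing
are out of scope; depth at a variant site is defined as the bedGraph
value at POS, the simplest consistent rule for low-depth accounting;
symbolic alleles are not modelled.
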