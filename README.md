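# ampliqc

Benchmarking, error characterization and quality-filter tuning for
variant call sets from amplicon-based exome sequencing on semiconductor
(flow-space) platforms.

## The problem

Amplicon exome sequencing on flow-space chemistry calls SNPs accurately
but produces many false-positive small indels, concentrated in
homopolymer/short-repeat contexts and mostly specific to a single
sequencing run. Assessing such data against a gold-standard truth set,
and deriving filters that clean it, involves a chain of steps that must
each be exact:

1. **Normalization** — split multiallelic VCF records (tracking
   `N_ORIG_ALTS`) and left-align indels to their minimal, left-most
   representation with one anchor base.
2. **Benchmarking** — restrict calls and truth to high-confidence ∩
   target (CDS ± 3 bp) regions and match by exact
   `(chrom, pos, ref, alt)` keys, separately for SNPs and indels:

   sensitivity = TP/(TP+FN), FDR = FP/(TP+FP) = 1 − precision,
   F1 = 2·precision·sensitivity/(precision+sensitivity).
3. **Error characterization** — multiallelic structure of false calls,
   indel-length classes (1–2 bp / 3–100 bp / >100 bp), false negatives
   explained by site depth < 10 reads, cross-sample recurrence of TP
   versus FP.
4. **Coverage analysis** — breadth at 20×, uniformity, IQR; per-amplicon
   GC statistics (high > 75 %, low < 25 %) and GC dropout;
   hard-to-sequence exons (always < 10 reads, or covered fraction always
   below 0.5/0.25/0.1); Bernoulli read downsampling with fits of
   `breadth(mean) = 1 − exp(−(mean − m₀)/τ)` and
   `loss = a + b·breadth`.
5. **Filter tuning** — exhaustive search over per-parameter threshold
   grids (SNP: GQ, FDP, QUAL, STB, FAO; indel: GQ, FDP, QUAL, HRUN,
   FAO) for the combination that maximizes FP removal subject to
   retaining ≥ 99 / 95 / 90 % of training TPs (low / medium / high
   stringency). A call is removed iff any one-sided condition fails.

A first-class synthetic-cohort generator reproduces the platform's
error structure (run-specific FPs, multiallelic FP indels, low-depth
FNs, GC dropout), so the whole pipeline is testable offline; the
generator's sidecar labels double as an oracle for the benchmarking
code.

## Worked example

```r
library(ampliqc)

cfg <- sim_config(seed = 42L)          # 9 samples, 980 SNP + 20 indel truth
cohort <- make_cohort(cfg)
#> Synthetic cohort: 9 samples, 1000 truth variants (980 SNP / 20 indel), 1059 amplicons

core <- intersect_intervals(cohort$regions$high_confidence,
                            cohort$regions$cds)
s1 <- cohort$samples$S1
norm <- restrict_to_regions(
  normalize_variants(s1$calls, cohort$reference$seq), core)

match_to_truth(norm, cohort$truth$variants, "SNP")
#> Benchmark (SNP): TP 951  FP 55  FN 29 | sensitivity 0.9704  FDR 0.0547  F1 0.9577
match_to_truth(norm, cohort$truth$variants, "indel")
#> Benchmark (indel): TP 14  FP 26  FN 6 | sensitivity 0.7000  FDR 0.6500  F1 0.4667
```

The indel class shows the platform's signature: decent SNP accuracy,
indel FDR above 0.5 before filtering. Tuning a medium-stringency SNP
filter on the labelled calls:

```r
calls <- label_calls(norm, cohort$truth$variants)
tune_thresholds(calls, "SNP", target_retention = 0.95)
#> Tuned SNP filter (target retention 0.95): TP retained 1.0000, FP removed 1.0000
#> Filter spec (SNP, medium-stringency):
#>   gq_min = 10
#>   fdp_min = -Inf
#>   qual_min = -Inf
#>   stb_max = 0.877269
#>   fao_min = 14
```

and the recurrence structure across the nine samples — true positives
recur almost everywhere, false positives are mostly private to one run:

```r
recurrence_profile(lapply(cohort$samples, function(x) x$labels))$summary
#>   n_samples frac_tp_recurrence_ge_nm1 frac_fp_recurrence_eq_1
#>           9                     0.953                   0.702
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the full study,
each a thin script over the package that prints what it finds and
writes its tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_cohort.R` | builds the nine-sample cohort and writes FASTA/BED/VCF/bedGraph artifacts |
| `02_target_audit.R` | audits a (degraded) capture design against the gene model: missed/partial exons per gene |
| `03_benchmark.R` | per-sample SNP/indel accuracy against the truth set |
| `04_error_profiles.R` | 11-parameter distributions by label, multiallelic/low-depth error shares, recurrence |
| `05_coverage_downsampling.R` | coverage summaries, GC-stratified amplicon stats, hard exons, 90→20× titration and curve fits |
| `06_filter_tuning.R` | derives the three stringency filters and tests them on a held-out cohort |

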