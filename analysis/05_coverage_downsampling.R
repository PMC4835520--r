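#!/usr/bin/env Rscript
# Step 5 — coverage statistics, hard-to-sequence exons, GC bias, and the
# downsampling titration.
#
# Computes per-sample coverage summaries (mean, breadth at 20x,
# uniformity, IQR), per-amplicon GC-stratified statistics, the exons
# that stay under-covered in every sample, and then thins one sample's
# reads to 90..20x, fitting breadth(mean) = 1 - exp(-(mean - m0)/tau)
# and loss(breadth) = a + b*breadth.

suppressPackageStartupMessages({
  library(ampliqc)
  library(dplyr)
})

cfg <- sim_config(seed = 20260921L)
cohort <- make_cohort(cfg)
targets <- cohort$regions$targets
dir.create("results", showWarnings = FALSE)

cov <- bind_rows(lapply(names(cohort$samples), function(nm) {
  mutate(region_depth_summary(cohort$samples[[nm]]$depth, targets),
         sample = nm, .before = 1)
}))
write.table(cov, "results/coverage_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(cov)

# per-amplicon statistics, averaged over samples, stratified by GC class
amp_stats <- bind_rows(lapply(names(cohort$samples), function(nm) {
  mutate(amplicon_stats(cohort$samples[[nm]]$reads,
                        cohort$regions$amplicons, cohort$reference$seq),
         sample = nm)
}))
amp_mean <- amp_stats %>%
  group_by(amp_id, gc, gc_class) %>%
  summarise(mean_depth = mean(mean_depth),
            reads_per_million = mean(reads_per_million), .groups = "drop")
write.table(amp_mean, "results/amplicon_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
gc_tab <- amp_mean %>%
  group_by(gc_class) %>%
  summarise(n = n(), median_depth = median(mean_depth),
            frac_below_10 = mean(mean_depth < 10))
print(gc_tab)

# hard-to-sequence exons across the cohort
exons <- cohort$regions$exons
cov_table <- bind_rows(lapply(names(cohort$samples), function(nm) {
  mutate(exon_coverage(cohort$samples[[nm]]$depth, exons), sample = nm)
}))
hard <- hard_region_classifier(cov_table)
write.table(hard$classes, "results/hard_exons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(hard$summary)

# downsampling titration on the first sample
s <- cohort$samples$S1
series <- run_downsample_series(s$reads, targets, cohort$truth$variants,
                                levels = c(90, 80, 70, 60, 50, 40, 30, 20),
                                seed = 33L)
fit <- fit_coverage_curves(series)
write.table(series, "results/downsample_series.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(series)
cat(sprintf(
  "breadth curve: m0 %.1f, tau %.1f (r2 %.3f); loss line: slope %.3f (r2 %.3f)\n",
  fit$exponential$m0, fit$exponential$tau, fit$exponential$r2,
  fit$linear$slope, fit$linear$r2))
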