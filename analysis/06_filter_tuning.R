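#!/usr/bin/env Rscript
# Step 6 — derive the stringency filters and test them on held-out data.
#
# Trains low/medium/high-stringency five-parameter filters (SNP: GQ,
# FDP, QUAL, STB, FAO; indel: GQ, FDP, QUAL, HRUN, FAO) on the
# benchmark-scale training cohort, targeting 99/95/90 % TP retention,
# then applies the tuned specs to a held-out cohort drawn from the same
# study conditions with a different seed and reports retained TP and
# filtered FP fractions, the generalization test.

suppressPackageStartupMessages({
  library(ampliqc)
  library(dplyr)
})

train <- make_cohort(tuning_training_config(seed = 20260921L))
heldout <- make_cohort(tuning_training_config(seed = 20260922L))
train_calls <- cohort_labelled_calls(train, 1)
test_calls <- cohort_labelled_calls(heldout, 1)
dir.create("results", showWarnings = FALSE)

rows <- list()
specs <- list()
for (target in c(low = 0.99, medium = 0.95, high = 0.90)) {
  stringency <- names(which(c(low = 0.99, medium = 0.95,
                              high = 0.90) == target))
  for (cls in c("SNP", "indel")) {
    tr <- tune_thresholds(train_calls, cls, target_retention = target)
    specs[[paste(cls, stringency)]] <- tr$spec
    ts <- ampliqc:::filter_class(test_calls, cls)
    ap <- apply_filter(ts, tr$spec)
    rows[[paste(cls, stringency)]] <- tibble::tibble(
      variant_class = cls, stringency = stringency,
      target_retention = target,
      train_tp_retained = tr$train_retention,
      train_fp_filtered = tr$train_fp_removal,
      test_tp_retained = mean(ap$calls$filter[ts$label == "TP"] == "PASS"),
      test_fp_filtered = mean(ap$calls$filter[ts$label == "FP"] != "PASS"))
  }
}
report <- bind_rows(rows)
write.table(report, "results/filter_tuning.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(report, n = Inf)

# tuned thresholds, in the preset config format
lines <- character()
for (nm in names(specs)) {
  sp <- specs[[nm]]
  key <- paste0(tolower(sub(" .*", "", nm)), ".", sub(".* ", "", nm))
  for (thr in names(sp$thresholds)) {
    lines <- c(lines, sprintf("%s.%s = %g", key, thr, sp$thresholds[[thr]]))
  }
}
writeLines(lines, "results/tuned_thresholds.cfg")
cat("wrote results/filter_tuning.tsv and results/tuned_thresholds.cfg\n")
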