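# Benchmarking normalized call sets against a truth set. Matching is
# allele-level: a call is a true positive iff a truth record shares its
# exact (chrom, pos, ref, alt) key after normalization. Genotype/zygosity
# is deliberately ignored. SNPs and indels are evaluated separately;
# complex (equal-length multi-base) substitutions are excluded from both.

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

# internal: subset a normalized tibble to one benchmark class
filter_class <- function(x, variant_class) {
  cls <- x[["variant_class"]] %||% classify_alleles(x$ref, x$alt)
  if (variant_class == "SNP") {
    x[cls == "SNP", ]
  } else {
    x[cls %in% c("insertion", "deletion"), ]
  }
}

#' Accuracy statistics from benchmark counts
#'
#' Sensitivity = TP/(TP+FN); precision = TP/(TP+FP); FDR = 1 - precision;
#' F1 = harmonic mean of precision and sensitivity. With no calls at all
#' (TP+FP = 0) precision is reported as 1, FDR as 0 and F1 as 0, with a
#' warning. TP+FN = 0 is rejected: an empty evaluated truth set means the
#' benchmark region is wrong.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return One-row tibble with counts and rates.
#' @export
accuracy_stats <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fn == 0) {
    stop("TP + FN = 0: no truth variants in the evaluated region")
  }
  sens <- tp / (tp + fn)
  if (tp + fp == 0) {
    warning("no calls (TP + FP = 0); precision reported as 1, F1 as 0")
    prec <- 1
    f1 <- 0
  } else {
    prec <- tp / (tp + fp)
    f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  }
  tibble(tp = tp, fp = fp, fn = fn, sensitivity = sens, precision = prec,
         fdr = 1 - prec, f1 = f1)
}

#' Match a normalized call set to a truth set
#'
#' @param calls,truth Normalized, region-restricted variant tibbles
#'   (single-alt records; see [normalize_variants()]).
#' @param variant_class `"SNP"` or `"indel"`.
#' @return A benchmark result: list with `variant_class`, tibbles `tp`,
#'   `fp` (subsets of `calls`), `fn` (subset of `truth`), and `stats` from
#'   [accuracy_stats()].
#' @export
match_to_truth <- function(calls, truth, variant_class = c("SNP", "indel")) {
  variant_class <- match.arg(variant_class)
  if (nrow(calls) > 0 && any(grepl(",", calls$alt, fixed = TRUE))) {
    stop("un-normalized (multiallelic) call records; normalize first")
  }
  if (nrow(truth) > 0 && any(grepl(",", truth$alt, fixed = TRUE))) {
    stop("un-normalized (multiallelic) truth records; normalize first")
  }
  calls_c <- filter_class(calls, variant_class)
  truth_c <- filter_class(truth, variant_class)
  if (nrow(truth_c) == 0) {
    stop("truth set contains no ", variant_class,
         " variants in the evaluated region")
  }
  ck <- variant_key(calls_c)
  tk <- variant_key(truth_c)
  if (anyDuplicated(ck)) stop("duplicate keys in call set")
  if (anyDuplicated(tk)) stop("duplicate keys in truth set")
  is_tp <- ck %in% tk
  res <- list(
    variant_class = variant_class,
    tp = calls_c[is_tp, ],
    fp = calls_c[!is_tp, ],
    fn = truth_c[!(tk %in% ck), ]
  )
  res$stats <- accuracy_stats(nrow(res$tp), nrow(res$fp), nrow(res$fn))
  class(res) <- "benchmark_result"
  res
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "Benchmark (%s): TP %d  FP %d  FN %d | sensitivity %.4f  FDR %.4f  F1 %.4f\n",
    x$variant_class, x$stats$tp, x$stats$fp, x$stats$fn,
    x$stats$sensitivity, x$stats$fdr, x$stats$f1))
  invisible(x)
}

#' Cross-sample recurrence of labelled variants
#'
#' Counts, for every distinct normalized variant key, the number of
#' samples in which it appears, tabulated separately for TP and FP labels.
#' A variant labelled TP in one sample and FP in another indicates the
#' samples were benchmarked against different truth sets and is rejected.
#'
#' @param labelled_sets Named list (one element per sample) of tibbles
#'   with key columns `chrom`, `pos`, `ref`, `alt` and a `label` column
#'   (`"TP"`/`"FP"`; other labels are ignored).
#' @return List with `histogram` (tibble label, recurrence, n_variants)
#'   and `summary` (fraction of distinct TP seen in >= n_samples - 1
#'   samples, fraction of distinct FP seen in exactly one sample).
#' @export
recurrence_profile <- function(labelled_sets) {
  stopifnot(length(labelled_sets) >= 2)
  n_samples <- length(labelled_sets)
  pooled <- bind_rows(labelled_sets, .id = "sample") %>%
    filter(.data$label %in% c("TP", "FP")) %>%
    mutate(key = variant_key(.))
  conflicting <- pooled %>%
    distinct(.data$key, .data$label) %>%
    count(.data$key) %>%
    filter(.data$n > 1)
  if (nrow(conflicting) > 0) {
    stop("inconsistent labels across samples (same variant both TP and FP); ",
         "samples must share one truth set")
  }
  per_variant <- pooled %>%
    distinct(.data$key, .data$label, .data$sample) %>%
    count(.data$key, .data$label, name = "recurrence")
  if (any(per_variant$recurrence > n_samples)) {
    stop("recurrence exceeds the number of samples (duplicate keys within a sample)")
  }
  hist <- per_variant %>%
    count(.data$label, .data$recurrence, name = "n_variants") %>%
    arrange(.data$label, .data$recurrence)
  frac_of <- function(lab, pred) {
    v <- per_variant[per_variant$label == lab, ]
    if (nrow(v) == 0) return(NA_real_)
    mean(pred(v$recurrence))
  }
  list(
    histogram = hist,
    summary = tibble(
      n_samples = n_samples,
      frac_tp_recurrence_ge_nm1 = frac_of("TP", function(r) r >= n_samples - 1),
      frac_fp_recurrence_eq_1 = frac_of("FP", function(r) r == 1)
    )
  )
}

#' Characterize benchmark errors
#'
#' Computes, from a benchmark result: the fractions of TP and FP calls
#' originating from multiallelic records (>= 2 and >= 3 alternate alleles,
#' via `n_original_alts`); the indel-length histogram per label in classes
#' 1-2 bp, 3-100 bp, > 100 bp; and the fraction of false negatives whose
#' site depth is below 10 reads. FN sites not covered by the depth track
#' are counted as depth 0 by bedGraph semantics only when the track spans
#' them; sites outside the track are reported separately as unknown.
#'
#' @param result A benchmark result from [match_to_truth()].
#' @param depth A depth track (tibble `chrom`, `start`, `end`, `depth`) or
#'   `NULL` to skip the FN depth analysis.
#' @param low_depth_threshold Depth below which an FN counts as
#'   low-coverage (default 10 reads).
#' @return List with `multiallelic`, `indel_length` and `fn_low_depth`
#'   tibbles.
#' @export
error_profile <- function(result, depth = NULL, low_depth_threshold = 10) {
  stopifnot(inherits(result, "benchmark_result"))
  ma_row <- function(x, lab) {
    noa <- x[["n_original_alts"]] %||% rep(NA_integer_, nrow(x))
    tibble(
      label = lab,
      n = nrow(x),
      frac_ge2_alts = if (nrow(x) == 0) NA_real_ else
        mean(noa >= 2, na.rm = TRUE),
      frac_ge3_alts = if (nrow(x) == 0) NA_real_ else
        mean(noa >= 3, na.rm = TRUE)
    )
  }
  multiallelic <- bind_rows(ma_row(result$tp, "TP"), ma_row(result$fp, "FP"))

  len_row <- function(x, lab) {
    il <- x[["indel_length"]] %||% abs(nchar(x$ref) - nchar(x$alt))
    il <- il[il > 0]
    tibble(
      label = lab,
      length_class = c("1-2bp", "3-100bp", ">100bp"),
      n = c(sum(il <= 2), sum(il > 2 & il <= 100), sum(il > 100))
    )
  }
  indel_length <- bind_rows(
    len_row(result$tp, "TP"), len_row(result$fp, "FP"),
    len_row(result$fn, "FN"))

  if (is.null(depth) || nrow(result$fn) == 0) {
    fn_low <- tibble(n_fn = nrow(result$fn), n_low_depth = NA_integer_,
                     n_unknown_depth = NA_integer_,
                     frac_low_depth = NA_real_)
  } else {
    d <- depth_at(depth, result$fn$chrom, result$fn$pos)
    known <- !is.na(d)
    fn_low <- tibble(
      n_fn = nrow(result$fn),
      n_low_depth = sum(d[known] < low_depth_threshold),
      n_unknown_depth = sum(!known),
      frac_low_depth = if (any(known)) {
        sum(d[known] < low_depth_threshold) / sum(known)
      } else NA_real_
    )
  }
  list(multiallelic = multiallelic, indel_length = indel_length,
       fn_low_depth = fn_low)
}

#' Label calls by truth membership
#'
#' Convenience for filter tuning: appends a `label` column (`"TP"`/`"FP"`)
#' to a normalized call set by exact-key comparison with a normalized
#' truth set.
#'
#' @param calls,truth Normalized variant tibbles.
#' @return `calls` with a `label` column.
#' @export
label_calls <- function(calls, truth) {
  calls$label <- ifelse(variant_key(calls) %in% variant_key(truth),
                        "TP", "FP")
  calls
}
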