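norm_tbl <- function(chrom, pos, ref, alt, ...) {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt, ...)
}

test_that("exact-key matching partitions calls and truth correctly", {
  truth <- norm_tbl("chr1", c(105L, 300L), c("A", "C"), c("T", "G"))
  # calls identical to truth: perfect scores
  r <- match_to_truth(truth, truth, "SNP")
  expect_equal(r$stats$fp, 0L)
  expect_equal(r$stats$fn, 0L)
  expect_equal(r$stats$sensitivity, 1)
  # off-by-one position: FP + FN
  calls <- norm_tbl("chr1", 106L, "A", "T")
  r2 <- match_to_truth(calls, truth, "SNP")
  expect_equal(c(r2$stats$tp, r2$stats$fp, r2$stats$fn), c(0L, 1L, 2L))
  # same position, different alt: FP + FN
  calls3 <- norm_tbl("chr1", 105L, "A", "G")
  r3 <- match_to_truth(calls3, truth, "SNP")
  expect_equal(c(r3$stats$tp, r3$stats$fp), c(0L, 1L))
  # multiallelic input rejected
  expect_error(match_to_truth(norm_tbl("chr1", 1L, "A", "T,G"), truth,
                              "SNP"), "normalize")
})

test_that("accuracy statistics follow the stated formulas and
           conventions", {
  s <- accuracy_stats(10, 0, 0)
  expect_equal(c(s$sensitivity, s$fdr, s$f1), c(1, 0, 1))
  s2 <- accuracy_stats(90, 10, 10)
  expect_equal(c(s2$sensitivity, s2$fdr, s2$f1), c(0.9, 0.1, 0.9))
  s3 <- accuracy_stats(0, 5, 5)
  expect_equal(c(s3$sensitivity, s3$fdr, s3$f1), c(0, 1, 0))
  expect_warning(s4 <- accuracy_stats(0, 0, 5), "no calls")
  expect_equal(c(s4$precision, s4$fdr, s4$f1), c(1, 0, 0))
  expect_error(accuracy_stats(0, 3, 0), "TP \\+ FN")
  # FDR + precision = 1 and F1 equals the harmonic mean, on random counts
  withr::with_seed(51, {
    for (i in 1:20) {
      tp <- sample(0:100, 1); fp <- sample(0:50, 1); fn <- sample(1:50, 1)
      st <- accuracy_stats(tp, fp, fn)
      expect_equal(st$fdr + st$precision, 1)
      hm <- if (st$precision + st$sensitivity == 0 || tp + fp == 0) 0 else
        2 / (1 / st$precision + 1 / st$sensitivity) *
        (st$precision * st$sensitivity > 0)
      if (tp > 0) {
        expect_equal(st$f1, 2 / (1 / st$precision + 1 / st$sensitivity))
      }
    }
  })
})

test_that("benchmarking a synthetic sample reproduces generator labels
           exactly", {
  co <- small_cohort()
  core <- intersect_intervals(co$regions$high_confidence, co$regions$cds)
  truth_norm <- co$truth$variants
  for (sname in names(co$samples)) {
    s <- co$samples[[sname]]
    norm <- restrict_to_regions(
      normalize_variants(s$calls, co$reference$seq), core)
    lab <- s$labels
    for (cls in c("SNP", "indel")) {
      r <- match_to_truth(norm, truth_norm, cls)
      pick <- function(df, what) {
        cls_match <- if (cls == "SNP") {
          nchar(df$ref) == 1 & nchar(df$alt) == 1
        } else {
          nchar(df$ref) != nchar(df$alt)
        }
        sort(ampliqc:::variant_key(df[df$label == what & cls_match, ]))
      }
      expect_identical(sort(ampliqc:::variant_key(r$tp)), pick(lab, "TP"))
      expect_identical(sort(ampliqc:::variant_key(r$fp)), pick(lab, "FP"))
      expect_identical(sort(ampliqc:::variant_key(r$fn)), pick(lab, "FN"))
    }
  }
})

test_that("recurrence profile matches brute-force counting and exposes
           the summary fractions", {
  # variant present in all samples has recurrence n_samples
  sets <- lapply(1:9, function(i) {
    norm_tbl("chr1", 10L, "A", "T", label = "TP")
  })
  r <- recurrence_profile(sets)
  expect_equal(r$histogram$recurrence, 9L)
  expect_equal(r$summary$frac_tp_recurrence_ge_nm1, 1)
  # random synthetic sets vs brute force
  withr::with_seed(61, {
    pool_tp <- norm_tbl("chr1", seq(100L, 1000L, by = 10L), "A", "T")
    pool_fp <- norm_tbl("chr1", seq(2000L, 2900L, by = 10L), "C", "G")
    sets <- lapply(1:5, function(i) {
      dplyr::bind_rows(
        dplyr::mutate(pool_tp[runif(nrow(pool_tp)) < 0.8, ], label = "TP"),
        dplyr::mutate(pool_fp[runif(nrow(pool_fp)) < 0.2, ], label = "FP"))
    })
  })
  r2 <- recurrence_profile(sets)
  brute <- table(unlist(lapply(sets, function(s) {
    unique(paste(s$label, s$pos))
  })))
  for (lab in c("TP", "FP")) {
    want <- table(brute[grepl(lab, names(brute))])
    got <- r2$histogram[r2$histogram$label == lab, ]
    expect_equal(got$n_variants, as.integer(want),
                 ignore_attr = TRUE)
  }
  expect_true(is.numeric(r2$summary$frac_tp_recurrence_ge_nm1))
  # conflicting labels across samples are rejected
  bad <- list(norm_tbl("chr1", 5L, "A", "T", label = "TP"),
              norm_tbl("chr1", 5L, "A", "T", label = "FP"))
  expect_error(recurrence_profile(bad), "inconsistent")
})

test_that("error profile computes multiallelic, length and low-depth
           fractions", {
  truth <- norm_tbl("chr1", c(100L, 200L, 300L), c("A", "C", "G"),
                    c("T", "G", "A"))
  calls <- norm_tbl("chr1", c(100L, 400L), c("A", "T"), c("T", "C"),
                    n_original_alts = c(1L, 3L))
  r <- match_to_truth(calls, truth, "SNP")
  depth <- tibble::tibble(chrom = "chr1", start = c(0L, 250L),
                          end = c(250L, 1000L), depth = c(50, 7))
  ep <- error_profile(r, depth)
  expect_equal(ep$multiallelic$frac_ge3_alts[ep$multiallelic$label == "FP"], 1)
  expect_equal(ep$multiallelic$frac_ge3_alts[ep$multiallelic$label == "TP"], 0)
  # FN at pos 200 has depth 50, FN at 300 has depth 7 -> half low-depth
  expect_equal(ep$fn_low_depth$frac_low_depth, 0.5)
  expect_equal(ep$fn_low_depth$n_low_depth, 1L)
  # no multiallelic calls -> fraction 0
  r0 <- match_to_truth(norm_tbl("chr1", 100L, "A", "T",
                                n_original_alts = 1L), truth, "SNP")
  ep0 <- error_profile(r0)
  expect_equal(ep0$multiallelic$frac_ge2_alts, c(0, NaN),
               ignore_attr = TRUE)
  # indel length classes: ref A alt ATT is a 2 bp insertion, class 1-2bp
  tri <- norm_tbl("chr1", c(100L, 200L), c("A", "C"),
                  c("ATT", paste0("C", strrep("T", 120))))
  truth_i <- norm_tbl("chr1", 500L, "A", "AT")
  ri <- match_to_truth(tri, truth_i, "indel")
  epi <- error_profile(ri)
  fp_hist <- epi$indel_length[epi$indel_length$label == "FP", ]
  expect_equal(fp_hist$n[fp_hist$length_class == "1-2bp"], 1L)
  expect_equal(fp_hist$n[fp_hist$length_class == ">100bp"], 1L)
})
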