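# random labelled callset used by the monotonicity / idempotence suite
random_labelled_calls <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 10L, ref = "A",
    alt = sample(c("T", "AT"), n, replace = TRUE),
    variant_class = NA_character_,
    label = sample(c("TP", "FP"), n, replace = TRUE, prob = c(0.8, 0.2)),
    gq = round(runif(n, 1, 99)), fdp = round(runif(n, 5, 300)),
    qual = runif(n, 5, 3000), fao = round(runif(n, 1, 150)),
    stb = runif(n, 0.5, 1), hrun = rpois(n, 2)
  ) |> dplyr::mutate(
    variant_class = ifelse(alt == "T", "SNP", "insertion")))
}

test_that("shipped presets parse into monotone-stringency filter specs", {
  ps <- filter_presets()
  expect_setequal(names(ps), c("indel_low", "indel_medium", "indel_high",
                               "snp_low", "snp_medium", "snp_high"))
  expect_equal(ps$snp_low$thresholds$stb_max, 0.90)
  expect_equal(ps$indel_low$thresholds$hrun_max, 6)
  expect_equal(ps$snp_high$target_retention, 0.90)
  # raising stringency never relaxes a threshold
  for (cls in c("snp", "indel")) {
    for (nm in names(ps[[paste0(cls, "_low")]]$thresholds)) {
      v <- vapply(paste0(cls, c("_low", "_medium", "_high")),
                  function(k) ps[[k]]$thresholds[[nm]], numeric(1))
      if (grepl("_min$", nm)) {
        expect_true(all(diff(v) >= 0), info = paste(cls, nm))
      } else {
        expect_true(all(diff(v) <= 0), info = paste(cls, nm))
      }
    }
  }
})

test_that("filter application removes on any failing condition and
           reports missing parameters separately", {
  ps <- filter_presets()
  # SNP with STB 0.95 under the low-stringency preset is removed
  snp <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "T",
                        gq = 50, fdp = 100, qual = 500, fao = 30,
                        stb = 0.95)
  r <- apply_filter(snp, ps$snp_low)
  expect_equal(nrow(r$removed), 1L)
  expect_equal(r$removed$filter, "ts_low")
  # clearing every threshold: retained with PASS
  snp$stb <- 0.6
  r2 <- apply_filter(snp, ps$snp_low)
  expect_equal(r2$retained$filter, "PASS")
  # indel GQ below gq_min is removed
  ind <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "AT",
                        gq = 3, fdp = 100, qual = 500, fao = 30, hrun = 1)
  spec <- filter_spec("indel", list(gq_min = 5, fdp_min = 0, qual_min = 0,
                                    hrun_max = 10, fao_min = 0))
  expect_equal(nrow(apply_filter(ind, spec)$removed), 1L)
  # missing required parameter -> ts_missing
  ind2 <- dplyr::mutate(ind, hrun = NA_real_)
  r3 <- apply_filter(ind2, spec)
  expect_equal(r3$calls$filter, "ts_missing")
  expect_equal(r3$counts$n_missing, 1L)
})

test_that("filters are monotone in thresholds and idempotent across 200
           random specs", {
  calls <- random_labelled_calls(400, seed = 101)
  withr::with_seed(102, {
    for (i in 1:200) {
      cls <- sample(c("SNP", "indel"), 1)
      thr <- list(gq_min = runif(1, 0, 60), fdp_min = runif(1, 0, 150),
                  qual_min = runif(1, 0, 800), fao_min = runif(1, 0, 40))
      if (cls == "SNP") thr$stb_max <- runif(1, 0.5, 1) else
        thr$hrun_max <- runif(1, 0, 6)
      spec <- filter_spec(cls, thr)
      sub <- calls[calls$variant_class %in%
                     (if (cls == "SNP") "SNP" else "insertion"), ]
      r <- apply_filter(sub, spec)
      # idempotence: re-applying to the retained set removes nothing
      r2 <- apply_filter(r$retained, spec)
      expect_equal(nrow(r2$retained), nrow(r$retained))
      # monotonicity: tightening one threshold never grows the set
      nm <- sample(names(thr), 1)
      thr2 <- thr
      thr2[[nm]] <- if (grepl("_min$", nm)) thr2[[nm]] * 1.5 + 1 else
        thr2[[nm]] * 0.7
      rt <- apply_filter(sub, filter_spec(cls, thr2))
      expect_lte(nrow(rt$retained), nrow(r$retained))
      # and the retained set shrinks as a subset, not just in count
      expect_true(all(rt$retained$pos %in% r$retained$pos))
    }
  })
})

test_that("threshold search equals the brute-force oracle on a small
           grid and respects feasibility", {
  calls <- random_labelled_calls(50, seed = 111)
  snp <- calls[calls$variant_class == "SNP", ]
  probs <- c(0, 0.5, 1)
  res <- tune_thresholds(snp, "SNP", target_retention = 0.8,
                         candidate_probs = probs, presets = list())
  # brute-force enumeration over the same candidate grid
  tp <- snp[snp$label == "TP", ]
  fp <- snp[snp$label == "FP", ]
  pars <- list(gq = "min", fdp = "min", qual = "min", stb = "max",
               fao = "min")
  cand <- lapply(names(pars), function(p) {
    q <- quantile(tp[[p]], probs = probs, type = 8, names = FALSE)
    if (pars[[p]] == "min") sort(unique(c(-Inf, q))) else
      sort(unique(c(q, Inf)))
  })
  names(cand) <- names(pars)
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  keeps <- function(df, th) {
    df$gq >= th$gq & df$fdp >= th$fdp & df$qual >= th$qual &
      df$stb <= th$stb & df$fao >= th$fao
  }
  best <- -1L
  best_tp <- -1L
  for (i in seq_len(nrow(grid))) {
    th <- grid[i, ]
    ntp <- sum(keeps(tp, th))
    if (ntp < 0.8 * nrow(tp)) next
    rem <- nrow(fp) - sum(keeps(fp, th))
    if (rem > best || (rem == best && ntp > best_tp)) {
      best <- rem
      best_tp <- ntp
    }
  }
  expect_equal(res$train_fp_removal, best / nrow(fp))
  expect_equal(res$train_retention, best_tp / nrow(tp))
  # the selected spec applied to the training calls reproduces the
  # reported retention exactly
  ap <- apply_filter(snp[snp$label == "TP", ], res$spec)
  expect_equal(nrow(ap$retained) / nrow(tp), res$train_retention)
})

test_that("perfectly separable classes yield total FP removal at full
           retention", {
  n <- 60
  calls <- tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 5L, ref = "A", alt = "T",
    variant_class = "SNP",
    label = rep(c("TP", "FP"), each = n / 2),
    gq = c(runif(n / 2, 60, 99), runif(n / 2, 1, 20)),
    fdp = 100, qual = 500, fao = 30, stb = 0.6)
  res <- tune_thresholds(calls, "SNP", target_retention = 0.99,
                         presets = list())
  expect_equal(res$train_retention, 1)
  expect_equal(res$train_fp_removal, 1)
})

test_that("suspect-indel flags follow the advisory rules", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(1L, 2L, 3L), ref = c("A", "A", "A"),
    alt = c("AT", "AT", "ATT"),
    n_original_alts = c(3L, 1L, 1L),
    indel_length = c(1L, 120L, 2L),
    hrun = c(0, 0, 0))
  f <- flag_suspect_indels(calls)
  expect_equal(f$multiallelic_suspect, c(TRUE, FALSE, FALSE))
  expect_equal(f$long_indel_suspect, c(FALSE, TRUE, FALSE))
  expect_false(any(f$homopolymer_context))
  f2 <- flag_suspect_indels(dplyr::mutate(calls, hrun = c(5, 4, 6)))
  expect_equal(f2$homopolymer_context, c(TRUE, FALSE, TRUE))
})

test_that("parameter summaries expose all 11 caller parameters and match
           the sorted-order quantile oracle", {
  co <- small_cohort()
  lc <- cohort_labelled_calls(co, 1)
  s <- summarize_parameters(lc)
  expect_setequal(unique(s$summary$parameter),
                  c("AO", "DP", "FAO", "FDP", "FXX", "GQ", "HRUN", "QD",
                    "QUAL", "STB", "STBP"))
  # single call: all quantiles equal that value
  one <- summarize_parameters(lc[1, ])
  gq_row <- one$summary[one$summary$parameter == "GQ", ]
  expect_true(all(gq_row$quantile == lc$gq[1]))
  # quantiles match an independent sorted-order computation
  withr::with_seed(121, {
    x <- runif(100, 0, 50)
    fake <- tibble::tibble(label = "TP", gq = x)
    sq <- summarize_parameters(fake, probs = c(0.25, 0.5, 0.75))
    got <- sq$summary[sq$summary$parameter == "GQ", ]$quantile
    expect_equal(got, quantile(sort(x), c(0.25, 0.5, 0.75), type = 8,
                               names = FALSE))
  })
})
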