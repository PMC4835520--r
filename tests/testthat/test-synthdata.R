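test_that("reference generation is deterministic and carries the planted
           sequence structure", {
  cfg <- sim_config(seed = 3L, genome_length = 1e5, n_exons = 40,
                    n_homopolymer_runs = 20, n_triplet_repeats = 5,
                    n_truth_snps = 50, n_truth_indels = 5)
  r1 <- make_reference(cfg)
  r2 <- make_reference(cfg)
  expect_identical(as.character(r1$seq), as.character(r2$seq))
  # planted homopolymers are found by the linear-scan counter
  expect_gte(count_homopolymer_runs(r1$seq, 6), 20)
  # GC-designated blocks match their composition class
  for (cl in c("high", "low")) {
    b <- r1$blocks[r1$blocks$gc_class == cl, ]
    if (nrow(b) == 0) next
    gc <- gc_fraction(r1$seq, b$start[1], b$end[1])
    if (cl == "high") expect_gt(gc, 0.75) else expect_lt(gc, 0.25)
  }
  expect_error(sim_config(genome_length = 5e3), ">= 10 kb")
})

test_that("region sets tile exons with 1-2 amplicons of legal length", {
  co <- small_cohort()
  amp <- co$regions$amplicons
  rng <- co$cfg$amplicon_length_range
  expect_true(all(amp$end - amp$start >= rng[1]))
  expect_true(all(amp$end - amp$start <= rng[2]))
  expect_true(all(table(amp$exon_id) <= 2))
  # every CDS exon fully covered by amplicons, by per-base membership
  ex <- co$regions$exons
  for (i in sample.int(nrow(ex), 40)) {
    pos <- seq.int(ex$start[i], ex$end[i] - 1L)
    expect_true(all(points_in_intervals(co$regions$targets,
                                        rep(ex$chrom[i], length(pos)), pos)))
  }
  # BED round trip of the target set
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(co$regions$targets, f)
  expect_identical(read_bed(f), co$regions$targets)
  expect_error(
    sim_config(exon_length_range = c(100, 600),
               amplicon_length_range = c(156, 240)),
    "cannot be tiled")
})

test_that("truth generation hits requested counts, composition, and
           membership, deterministically", {
  cfg <- sim_config(seed = 5L, genome_length = 4e5, n_exons = 160,
                    n_truth_snps = 980, n_truth_indels = 20, n_samples = 2)
  ref <- make_reference(cfg)
  regions <- make_region_sets(cfg, ref)
  tr1 <- make_truth_variants(cfg, ref, regions)
  tr2 <- make_truth_variants(cfg, ref, regions)
  expect_identical(tr1$variants, tr2$variants)
  expect_equal(sum(tr1$variants$variant_class == "SNP"), 980L)
  expect_equal(sum(tr1$variants$variant_class != "SNP"), 20L)
  core <- intersect_intervals(regions$high_confidence, regions$cds)
  expect_true(all(points_in_intervals(core, tr1$variants$chrom,
                                      tr1$variants$pos - 1L)))
  # also inside high-confidence ∩ targets, the benchmark invariant
  ct <- intersect_intervals(regions$high_confidence, regions$targets)
  expect_true(all(points_in_intervals(ct, tr1$variants$chrom,
                                      tr1$variants$pos - 1L)))
  # left-aligned: normalization is a no-op
  re_norm <- left_align(tr1$variants, ref$seq)
  expect_identical(re_norm[c("pos", "ref", "alt")],
                   tr1$variants[c("pos", "ref", "alt")])
  expect_error(
    make_truth_variants(sim_config(seed = 5L, genome_length = 4e5,
                                   n_exons = 160, n_truth_snps = 50000),
                        ref, regions),
    "candidate positions")
})

test_that("depth simulation hits the configured mean and the GC dropout
           ordering; no-bias limit is uniform", {
  co <- small_cohort()
  cfg <- co$cfg
  s <- co$samples$S1
  expect_true(abs(s$realized_mean - cfg$mean_coverage) <
                0.1 * cfg$mean_coverage)
  stats <- amplicon_stats(s$reads, co$regions$amplicons, co$reference$seq)
  med <- tapply(stats$mean_depth, stats$gc_class, median)
  expect_lt(med[["high"]], med[["mid"]])
  # realized mean from summed read lengths over target bases
  expect_equal(s$realized_mean,
               sum(s$reads$end - s$reads$start) /
                 interval_width(co$regions$targets))
  # gc_dropout_strength 0: per-amplicon counts consistent with equal
  # per-base rates (chi-square goodness-of-fit not rejected at 0.001)
  cfg0 <- sim_config(seed = 9L, genome_length = 3e5, n_exons = 120,
                     n_truth_snps = 100, n_truth_indels = 10,
                     gc_dropout_strength = 0)
  ref0 <- make_reference(cfg0)
  reg0 <- make_region_sets(cfg0, ref0)
  dp0 <- make_depth_and_reads(cfg0, reg0, seed = 99L)
  st0 <- amplicon_stats(dp0$reads, reg0$amplicons, ref0$seq)
  expected <- dp0$lambda
  pval <- stats::chisq.test(st0$n_reads, p = expected / sum(expected))$p.value
  expect_gt(pval, 0.001)
  expect_error(make_depth_and_reads(
    sim_config(mean_coverage = 1) |> (\(x) { x$mean_coverage <- -5; x })(),
    reg0, seed = 1L), "positive")
})

test_that("generator is deterministic end to end, including emitted files", {
  cfg <- sim_config(seed = 13L, genome_length = 2e5, n_exons = 80,
                    n_truth_snps = 150, n_truth_indels = 15, n_samples = 2,
                    fp_per_sample_snp = 15, fp_per_sample_indel = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_cohort(cfg, dir = d1)
  make_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("callset respects conservation and the error-rate dials", {
  co <- small_cohort()
  cfg <- co$cfg
  truth_n <- nrow(co$truth$variants)
  for (s in co$samples) {
    n_tp <- sum(s$labels$label == "TP")
    n_fn <- sum(s$labels$label == "FN")
    expect_equal(n_tp + n_fn, truth_n)
  }
  # all error rates zero: emitted alleles equal truth alleles exactly
  cfg0 <- sim_config(seed = 17L, genome_length = 3e5, n_exons = 120,
                     n_truth_snps = 200, n_truth_indels = 20, n_samples = 1,
                     fn_rate_snp = 0, fn_rate_indel = 0,
                     fp_per_sample_snp = 0, fp_per_sample_indel = 0)
  co0 <- make_cohort(cfg0)
  calls0 <- co0$samples$S1$calls
  expect_identical(
    calls0[order(calls0$pos), c("chrom", "pos", "ref", "alt")],
    co0$truth$variants[order(co0$truth$variants$pos),
                       c("chrom", "pos", "ref", "alt")])
  # FN rate over replicates inside the binomial 99 % band
  cfg_fn <- sim_config(seed = 19L, genome_length = 6e5, n_exons = 240,
                       n_truth_snps = 2000, n_truth_indels = 0,
                       n_samples = 1, fn_rate_snp = 0.05,
                       fp_per_sample_snp = 0, fp_per_sample_indel = 0)
  ref <- make_reference(cfg_fn)
  regions <- make_region_sets(cfg_fn, ref)
  truth <- make_truth_variants(cfg_fn, ref, regions)
  dp <- make_depth_and_reads(cfg_fn, regions, seed = 1L)
  n_rep <- 25
  fns <- vapply(seq_len(n_rep), function(i) {
    cs <- make_callset(cfg_fn, truth, dp, sample_id = 1L,
                       seed = 1000L + i)
    sum(cs$labels$label == "FN") / 2000
  }, numeric(1))
  # every replicate inside the binomial 99 % band around 0.05
  band <- qbinom(c(0.005, 0.995), 2000, 0.05) / 2000
  expect_true(all(fns >= band[1] & fns <= band[2]))
  expect_equal(mean(fns), 0.05, tolerance = 1e-3)
})
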