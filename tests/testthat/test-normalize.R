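test_that("multiallelic splitting routes per-allele annotations", {
  rec <- tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "A", alt = "T,G",
    qual = 50, ao = "12,3", fao = "10,2", dp = 40, gq = 30)
  out <- split_multiallelic(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$n_original_alts, c(2L, 2L))
  expect_equal(out$alt, c("T", "G"))
  expect_equal(out$ao, c(12, 3))
  expect_equal(out$fao, c(10, 2))
  expect_equal(out$dp, c(40, 40))

  single <- tibble::tibble(chrom = "chr1", pos = 5L, ref = "C", alt = "T")
  expect_equal(split_multiallelic(single)$n_original_alts, 1L)
  # already-split records keep their original count
  pre <- tibble::tibble(chrom = "chr1", pos = 5L, ref = "C", alt = "T",
                        n_original_alts = 3L)
  expect_equal(split_multiallelic(pre)$n_original_alts, 3L)
  expect_error(split_multiallelic(tibble::tibble(
    chrom = "chr1", pos = 1L, ref = "A", alt = ".")), "without alternate")
  # split then merge-by-site reconstructs the original alt multiset
  expect_setequal(out$alt, strsplit(rec$alt, ",")[[1]])
})

test_that("left alignment matches the enumeration oracle and shifts a
           homopolymer deletion to its left-most representation", {
  # reference with positions 101..108 = T G G A A A A C
  g <- paste0(strrep("C", 100), "TGGAAAAC", strrep("C", 50))
  ref <- c(chr1 = g)
  v <- tibble::tibble(chrom = "chr1", pos = 106L, ref = "AA", alt = "A")
  out <- left_align(v, ref)
  expect_equal(out$pos, 103L)
  expect_equal(out$ref, "GA")
  expect_equal(out$alt, "G")
  expect_equal(out$variant_class, "deletion")
  expect_equal(out$indel_length, 1L)
  # SNP unchanged
  s <- left_align(tibble::tibble(chrom = "chr1", pos = 101L,
                                 ref = "T", alt = "A"), ref)
  expect_equal(s[c("pos", "ref", "alt")],
               tibble::tibble(pos = 101L, ref = "T", alt = "A"))
  # REF disagreement is rejected with the locus
  expect_error(left_align(tibble::tibble(chrom = "chr1", pos = 101L,
                                         ref = "G", alt = "A"), ref),
               "disagrees.*chr1:101")
})

test_that("normalization satisfies haplotype equivalence, left-most
           position and idempotence on randomized representations", {
  g <- random_genome(5000, seed = 21)
  ref <- c(chr1 = g)
  n_cases <- 1000
  withr::with_seed(22, {
    cases <- lapply(seq_len(n_cases), function(i) {
      pos <- sample(200:4500, 1)
      anchor <- substr(g, pos, pos)
      len <- sample(1:4, 1)
      if (runif(1) < 0.5) {
        r <- substr(g, pos, pos + len)
        a <- anchor
      } else {
        r <- anchor
        a <- paste0(anchor, paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = ""))
      }
      # denormalize: pad with reference context on both sides
      lpad <- sample(0:3, 1)
      rpad <- sample(0:3, 1)
      p2 <- pos - lpad
      pre <- substr(g, p2, pos - 1)
      post <- substr(g, pos + nchar(r), pos + nchar(r) + rpad - 1)
      tibble::tibble(chrom = "chr1", pos = p2,
                     ref = paste0(pre, r, post), alt = paste0(pre, a, post),
                     opos = pos, oref = r, oalt = a)
    })
    cases <- dplyr::bind_rows(cases)
  })
  out <- left_align(cases, ref)
  # haplotype equivalence against the padded representation
  for (i in sample.int(nrow(out), 200)) {
    expect_identical(
      apply_variant(g, out$pos[i], out$ref[i], out$alt[i]),
      apply_variant(g, cases$pos[i], cases$ref[i], cases$alt[i]))
  }
  # idempotence
  again <- left_align(out, ref)
  expect_identical(again[c("pos", "ref", "alt")], out[c("pos", "ref", "alt")])
  # left-most position: enumerate every anchor position in a window and
  # find, via prefix/suffix haplotype identity, the smallest position
  # admitting an equivalent representation of the same edit
  leftmost_oracle <- function(genome, hap, pos, window = 30L) {
    d <- nchar(hap) - nchar(genome)
    cand <- max(1L, pos - window):(pos + 5L)
    ok <- vapply(cand, function(p) {
      substr(hap, 1, p) == substr(genome, 1, p) &&
        (if (d > 0) {
          substr(hap, p + d + 1, nchar(hap)) ==
            substr(genome, p + 1, nchar(genome))
        } else {
          substr(genome, p - d + 1, nchar(genome)) ==
            substr(hap, p + 1, nchar(hap))
        })
    }, logical(1))
    min(cand[ok])
  }
  idx <- sample(which(out$variant_class != "SNP"), 200)
  for (i in idx) {
    hap <- apply_variant(g, out$pos[i], out$ref[i], out$alt[i])
    expect_equal(out$pos[i], leftmost_oracle(g, hap, out$pos[i]),
                 info = sprintf("case %d (%s)", i, out$variant_class[i]))
  }
})

test_that("normalization agrees with bcftools norm on a small fixture", {
  g <- random_genome(2000, seed = 31)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::DNAStringSet(g), "chr1"), fa, width = 60)
  system2("samtools", c("faidx", fa), stdout = FALSE, stderr = FALSE)
  withr::with_seed(32, {
    pos <- sort(sample(seq(100, 1800, by = 25), 30))
    recs <- dplyr::bind_rows(lapply(pos, function(p) {
      len <- sample(1:3, 1)
      if (runif(1) < 0.5) {
        tibble::tibble(chrom = "chr1", pos = p,
                       ref = substr(g, p, p + len), alt = substr(g, p, p))
      } else {
        tibble::tibble(chrom = "chr1", pos = p, ref = substr(g, p, p),
                       alt = paste0(substr(g, p, p),
                                    paste(sample(c("A", "C", "G", "T"), len,
                                                 replace = TRUE),
                                          collapse = "")))
      }
    }))
  })
  vcf_in <- file.path(dir, "in.vcf")
  write_vcf(recs, vcf_in, contigs = c(chr1 = 2000L))
  vcf_out <- file.path(dir, "norm.vcf")
  st <- system2("bcftools", c("norm", "-f", fa, "-o", vcf_out, vcf_in),
                stdout = FALSE, stderr = FALSE)
  expect_equal(st, 0L)
  theirs <- read_vcf(vcf_out)
  ours <- left_align(recs, c(chr1 = g))
  expect_identical(
    ours[order(ours$pos), c("pos", "ref", "alt")],
    theirs[order(theirs$pos), c("pos", "ref", "alt")])
})

test_that("region restriction keeps exactly the members", {
  regions <- interval_set("chr1", 100L, 200L)
  v <- tibble::tibble(chrom = "chr1", pos = 151L, ref = "A", alt = "T")
  expect_equal(nrow(restrict_to_regions(v, regions)), 1L)
  expect_equal(nrow(restrict_to_regions(v, interval_set(character()))), 0L)
  withr::with_seed(41, {
    vs <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 500, replace = TRUE),
      pos = sample.int(1000, 500, replace = TRUE),
      ref = "A", alt = "T")
    rset <- interval_set(random_intervals(20))
    got <- restrict_to_regions(vs, rset)
    want <- vs[paste0(vs$chrom, ":", vs$pos - 1L) %in%
                 oracle_base_set(rset), ]
    expect_identical(got, want)
  })
})

test_that("VCF round-trip preserves records and annotations", {
  co <- small_cohort()
  s <- co$samples$S1
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(s$calls, f, contigs = stats::setNames(
    co$cfg$genome_length, co$cfg$chrom))
  back <- read_vcf(f)
  expect_equal(nrow(back), nrow(s$calls))
  expect_equal(back$pos, s$calls$pos)
  expect_equal(back$ref, s$calls$ref)
  expect_equal(back$alt, s$calls$alt)
  expect_equal(back$ao, s$calls$ao)
  expect_equal(back$hrun, s$calls$hrun)
  expect_equal(back$gq, round(s$calls$gq), tolerance = 1e-9)
  expect_equal(back$stb, s$calls$stb, tolerance = 1e-5)
  expect_equal(back$n_original_alts, s$calls$n_original_alts)
})
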